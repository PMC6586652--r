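# Sequential threshold criteria per (group, sign).  All bounds are strict;
# "between" rows are open intervals (lo, hi).  Transcribed from a typeset
# table whose HTML rendering collapsed the column positions of many cells:
# the criterion names, bound values and per-row cell counts are as printed,
# but cells whose note says "column placement uncertain" were assigned to
# (group, sign) columns using the accepting-rejecting principle that a
# single criterion should cost at most ~5-10% of true drift dives.
# Verify against the typeset original before relying on this file.
group,sign,criterion,op,lo,hi,order_index,note
2.1.3.4,neg,t1,between,0.07,0.14,1,garbled source cell '(0.7 0.14)'; lower bound read as 0.07
2.1.3.4,pos,t1,lt,,0.14,1,
2.1.4.3,neg,t1,lt,,0.15,1,
2.1.4.3,pos,t1,lt,,0.14,1,
2.4.1.3,neg,t1,lt,,0.14,1,
2.4.1.3,pos,t1,lt,,0.14,1,
3.1.2.4,neg,t1,lt,,0.14,1,
3.1.2.4,pos,t1,lt,,0.12,1,
3.1.4.2,neg,t1,lt,,0.14,1,
3.1.4.2,pos,t1,lt,,0.12,1,
3.2.1.4,neg,t1,lt,,0.9,1,column placement uncertain
3.4.1.2,neg,t1,lt,,0.8,1,column placement uncertain
2.1.3.4,neg,d1,lt,,0.8,2,
2.1.3.4,pos,d1,lt,,0.7,2,
2.1.4.3,neg,d1,lt,,0.8,2,column placement uncertain
2.1.4.3,pos,d1,lt,,0.6,2,column placement uncertain
2.4.1.3,neg,d1,lt,,0.85,2,column placement uncertain
2.4.1.3,pos,d1,lt,,0.6,2,column placement uncertain
3.1.2.4,neg,d1,lt,,0.8,2,
3.1.2.4,pos,d1,lt,,0.8,2,
3.1.4.2,neg,d1,lt,,0.8,2,
2.1.3.4,neg,d4,lt,,0.8,3,
2.1.3.4,pos,d4,lt,,0.6,3,column placement uncertain
2.1.4.3,neg,d4,lt,,0.8,3,
2.1.4.3,pos,d4,lt,,0.7,3,column placement uncertain
3.1.2.4,neg,d4,lt,,0.8,3,
3.1.4.2,neg,d4,lt,,0.8,3,column placement uncertain
2.4.1.3,neg,d4,lt,,0.8,3,column placement uncertain
2.4.1.3,pos,d4,lt,,0.8,3,column placement uncertain
2.1.3.4,neg,mrratio,lt,,0.15,4,
2.1.3.4,pos,mrratio,lt,,0.2,4,
2.1.4.3,neg,mrratio,lt,,0.15,4,
2.1.4.3,pos,mrratio,lt,,0.3,4,
2.4.1.3,neg,mrratio,lt,,0.2,4,
2.4.1.3,pos,mrratio,lt,,0.2,4,
3.1.2.4,neg,mrratio,lt,,0.2,4,
2.1.3.4,neg,ps1,gt,0.4,,5,
2.1.3.4,pos,ps1,gt,0.4,,5,
2.1.4.3,neg,ps1,gt,0.4,,5,
2.1.4.3,pos,ps1,gt,0.4,,5,
2.4.1.3,neg,ps1,lt,,0.15,5,
2.4.1.3,pos,ps1,gt,0.4,,5,column placement uncertain
2.1.3.4,pos,t4,gt,0.9,,6,column placement uncertain
2.1.4.3,pos,t4,gt,0.9,,6,column placement uncertain
2.4.1.3,pos,t4,gt,0.85,,6,column placement uncertain
3.1.2.4,pos,t4,gt,0.85,,6,column placement uncertain
3.1.4.2,pos,t4,gt,0.8,,6,column placement uncertain
2.1.3.4,pos,mdepthr,between,0.6,1.4,7,column placement uncertain
2.1.4.3,pos,mdepthr,between,0.8,1.5,7,column placement uncertain
3.1.2.4,pos,mdepthr,between,0.8,1.3,7,column placement uncertain
3.1.4.2,pos,mdepthr,between,0.8,2,7,column placement uncertain
3.2.1.4,neg,sratio,lt,,10,8,column placement uncertain
4.2.1.3,neg,sratio,lt,,10,8,column placement uncertain
2.4.1.3,neg,sratio,between,2,7,8,column placement uncertain
3.2.1.4,neg,ps2,gt,0.4,,9,column placement uncertain
4.2.1.3,neg,ps2,gt,0.2,,9,column placement uncertain
4.2.1.3,pos,ps2,gt,0.45,,9,column placement uncertain
3.2.1.4,neg,ps3,lt,,0.2,10,column placement uncertain
2.1.3.4,neg,sdd,between,0.13,0.4,11,column placement uncertain
2.1.4.3,neg,sdd,between,0.1,0.3,11,column placement uncertain
2.1.3.4,neg,r1,lt,,0,12,column placement uncertain
3.4.1.2,pos,r1,lt,,0,12,column placement uncertain
3.4.1.2,pos,r4,lt,,0,13,column placement uncertain
3.4.1.2,neg,mdepthbias,lt,,0,14,column placement uncertain
3.1.4.2,pos,meand,lt,,0.8,15,column placement uncertain
3.2.1.4,neg,d2,lt,,0.8,16,applies in place of d1 for this group
3.4.1.2,pos,mdepthbias,lt,,-300,20,derived with tune_threshold on synthetic labelled dives; absent from the extracted source table
3.4.1.2,pos,ps3,gt,0.55,,21,derived with tune_threshold on synthetic labelled dives; absent from the extracted source table
2.1.4.3,neg,mdepthbias,gt,200,,20,derived with tune_threshold on synthetic labelled dives; absent from the extracted source table
2.1.3.4,neg,mdepthbias,gt,200,,20,derived with tune_threshold on synthetic labelled dives; absent from the extracted source table
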