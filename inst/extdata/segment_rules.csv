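# Per-group drifting-segment rules: first predicate (by priority) that
# fires assigns the segment.  Predicates are R expressions over the
# dive-shape variable names; "TRUE" rows are documented fallbacks.
# Proportional thresholds printed as "25" in the source table are
# proportions (0.25).  Rows marked "garbled source cell" were transcribed
# from a typeset table whose HTML rendering collapsed some cells; verify
# against the typeset original before relying on them.
group,priority,segment,predicate,note
2.1.3.4,1,1,mdepthbias > 0,
2.1.3.4,2,2,mdepthbias < 0,
2.1.3.4,3,1,TRUE,fallback (mdepthbias exactly 0)
2.1.4.3,1,1,ps1 > 0.25,
2.1.4.3,2,2,ps1 <= 0.25 & (1.1 * ps2) >= ps3,
2.1.4.3,3,3,ps1 <= 0.25 & (1.1 * ps2) < ps3,
2.1.4.3,4,2,TRUE,fallback (unreachable; rules exhaustive)
2.4.1.3,1,1,(mdepthbias < 0 & ps1 > ps3) | (mdepthbias > 0 & ps1 <= ps2),garbled source cell
2.4.1.3,2,2,mdepthbias < 0 & ps1 <= ps2,garbled source cell
2.4.1.3,3,3,mdepthbias > 0 & ps1 > ps2,garbled source cell
2.4.1.3,4,2,TRUE,fallback
3.1.2.4,1,3,ps1 < 0.25 & s > 0 & t < 0,garbled source cell
3.1.2.4,2,2,ps1 < 0.25 & s < 0 & t > 0,garbled source cell
3.1.2.4,3,1,avratio < 0,
3.1.2.4,4,2,avratio > 0,
3.1.2.4,5,1,TRUE,fallback
3.1.4.2,1,1,ps1 > 0.25,
3.1.4.2,2,2,ps1 < 0.25 & s < 0 & hp2 > hp3,garbled source cell
3.1.4.2,3,3,ps1 < 0.25 & s < 0 & hp2 < hp3,garbled source cell
3.1.4.2,4,1,TRUE,fallback
3.2.1.4,1,2,TRUE,all dives of this group drift on segment 2
3.4.1.2,1,1,mdepthbias > 0 & ps1 > ps2,
3.4.1.2,2,2,mdepthbias > 0 & ps1 < ps2,
3.4.1.2,3,3,mdepthbias < 0,
3.4.1.2,4,3,TRUE,fallback
4.2.1.3,1,1,mdepthbias >= 0,
4.2.1.3,2,2,mdepthbias < 0,
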