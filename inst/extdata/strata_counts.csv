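confounder,group,correct,incorrect
clothing,scrubs,3638,557
clothing,casual,2459,470
sex,male,4211,613
sex,female,1886,414
height,above_median,3925,550
height,below_median,2121,472
scenery,hospital,2934,282
scenery,regular,3163,745
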