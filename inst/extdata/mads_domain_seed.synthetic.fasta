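>mads_synthetic_seed01
MGRGRVELKRIENKINRQVTFAKRRNGLLKKAYELSVLCDAEVALIIFSNRGKLYEFCSS
>mads_synthetic_seed02
MGRGRVELKRIENKIIRVVIFAKRRNGLLQKAYEGSVLDDAEVALIIFSNRGKLYMFCSS
>mads_synthetic_seed03
MGRGKVELKRWENVINYQVTFAKRRNGLGKKAYESSVACDAEVALIIFSNRGKLYEFCSS
>mads_synthetic_seed04
MGWGRVELKRWENKINRQVMFCKRRNGLLKKAYELSVLCRAEVALIIFSNRGKLNEFMSS
>mads_synthetic_seed05
MFRGRVELKRIENKINRQVTFAKRRNGLLKKFYLLKMLCQAEVALIIFSNRGKLYEFCSN
>mads_synthetic_seed06
MGRGRDELKRIENKINRQVTNAKRRNGPLKTAYELSDLCDAEVALIIFSNRGKTYEFHSS
>mads_synthetic_seed07
MGRGRAELKNIENKINRQVTFYDRNNPLLKKAYELSVLCDAEVALIIFSNRGPLYEFCSS
>mads_synthetic_seed08
MGRGRVELKRIENKIQQQLRFAKRRNALLKKAYELQVLGDAEVALIIFSNRGKLYEFCSS
>mads_synthetic_seed09
MGRLRVELKSITNKINRQVTQACRRNGLEKKAYELSVLCDMEVALIIFSNRGKLYEFCSS
>mads_synthetic_seed10
MGRGRVELKRIINWHNRQVSFAKRRGGLLKKAYELSVLCDAEVALIAFSNRGKMYEFCSS
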