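CLUSTAL W (1.83) multiple sequence alignment


human      ARNDCEQGH-IKWLMFPSTWYV
cow        ARNDCKQGH-IKWLMFPSTWYV
goat       ARNDCKQGHPIKWLMFPSTWYV
mouse      ARNECEQGH-IKWLMFPSTWYV
                                 

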