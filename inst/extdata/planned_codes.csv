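category,prefix
chemotherapy,Z511
chemotherapy,Z512
organ_transplant,Z94
organ_transplant,T86
rehabilitation,Z50
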