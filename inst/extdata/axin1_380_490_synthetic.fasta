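>axin1_380-490_synthetic synthetic Axin-1-like segment, residues 380-490 (full-length numbering); designed stand-in, not the UniProt O15169 sequence
STSGSNESGTQEAQRAELAKQRARELAQALEAREALKAQLESGNTSQGSTNPGPSGPTPG
SSPGAQPSGPTGPSNGTPSGNEALRAQALKEAKLEAQARLESTGQNSGTSE
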