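BEGIN IONS
TITLE=two_mods
PEPMASS=528.259445
CHARGE=2+
918.452701 1.000000
805.368637 1.000000
690.341694 1.000000
619.304580 1.000000
518.256902 1.000000
389.214309 1.000000
274.187366 1.000000
175.118952 1.000000
251.150252 1.000000
881.399937 1.000000
END IONS
BEGIN IONS
TITLE=two_mods_plus_loss
PEPMASS=679.254445
CHARGE=2+
918.452701 1.000000
805.368637 1.000000
690.341694 1.000000
619.304580 1.000000
518.256902 1.000000
389.214309 1.000000
274.187366 1.000000
175.118952 1.000000
251.150252 1.000000
881.399937 1.000000
END IONS
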