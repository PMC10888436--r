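# Synthetic placeholder split-intein pair.
#
# These are NOT the Npu DnaE intein sequences. They are short synthetic
# placeholders that exercise the SIML construct logic (part ordering,
# translation round trips, cassette annotation) without presenting any
# invented sequence as a natural one. For a real synthesis order,
# replace int_c / int_n with the curated Npu DnaE C- and N-intein
# sequences from a primary database record.
int_c: MVKVIGRRSLGVQ
int_n: AEYCLSFGTEILTVEYG
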