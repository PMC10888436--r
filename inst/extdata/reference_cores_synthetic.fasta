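>enterocin_AS48 mature circular core, public record (topology=circular)
MAKEFGIPAAVAGTVLNVVEAGGWVTTIVSILTAVGSGGLSLLAAAGRESIKAYLKKEIKKKGKRAVIAW
>pumilarin_synthetic synthetic stand-in for the 70-aa mature pumilarin core, constructed to carry the published tryptic fragments (GLSLIAAAGK, YLKNEIK, junction AVIAWLAK) and the S37/G36 split site (topology=circular)
LAKEFGIPAAVAGTVLNVVEAGGWVTTIVSILTAVGSRGLSLIAAAGKESIKKYLKNEIKKKGKRAVIAW
>altitudin_A_synthetic synthetic stand-in for the 65-aa mature altitudin A core, constructed to carry the published tryptic fragments (GTGLVTAAMVATAK, junction YAAEWLATNLGISR) and the S8/I7 split site (topology=circular)
LATNLGISRKANEIVSLFNVAGSALTGVATGILSGIKGTGLVTAAMVATAKVAGAVSGLKYAAEW
>amylocyclicin_synthetic synthetic stand-in with circular-bacteriocin family composition (topology=circular)
LAGVLGSAIGAFSKLWAAFEAGVNAGQAVTDGLKAIGSNVATGVASGFTGLVRGASVLGKAIGW
>enterocin_NKR53B_synthetic synthetic stand-in with circular-bacteriocin family composition (topology=circular)
LWGNVLGALSNGAVRSTVQDLAKGIGSGAANAVLTGVGLVTAGAAFSKQVSKLANDAIPVIGKW
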