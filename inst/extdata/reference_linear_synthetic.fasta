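>closticin_574_synthetic synthetic stand-in for the 83-aa closticin-type linear bacteriocin; the N-terminal PDWSKIAA octapeptide is the published mature start, the remainder is constructed (topology=linear)
PDWSKIAAGSDKVGSAVGDTVKSAANTVSDFFTGKKPQESAVNAYNDGHKGKIDWGKVGAAAVGGALLGGVTYAVSHGLGKKA
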