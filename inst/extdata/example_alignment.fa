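>sample1
AG-CACAGTCAC
>sample2
AGACAC----AC
>sample3
AAACGCATTCAN
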