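>GLUD2_synthetic
ATGGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTCGAGGTCTGGGACCTAAGTTCGACCGT
TCGGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCGTAAGGCTGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTACAATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTGGCATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGCCCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTAGGGGTCTGATCCCTAAGATAGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGAGGCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTGATATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTCCATTCGACCGT
GCTGAAGGTCTGGGCCCTAAGATGGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCTCCAAGTCAGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGCCCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCTAA
>GLUD1_synthetic
ATGGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTGGTATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCGAAAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTACTATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCTGAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTGGTTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAACACTGATCCCTAAGTTCGACCGTGCTGAAGGTCCAATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTCATGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGTTCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAACTGCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCGACCGT
GCTGAAGGTCTGATCCCTAAGTTCGACCGTGCTGAAGGTCTGATCCCTAAGTTCTAA
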