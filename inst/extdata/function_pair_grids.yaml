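# Unordered allele-function-class pair -> gene phenotype.
# Keys are the two function classes joined by "|" after a C-locale sort;
# lookups sort the same way, so order of alleles never matters.
# CYP2C19/CYP2B6 use metabolizer labels; SLCO1B1 uses transporter-function
# labels. Pairs involving uncertain/unknown classes never reach the grid:
# the engine returns Indeterminate first.
version: "1.0"
grids:
  CYP2C19:
    increased|increased: Ultrarapid
    increased|normal: Rapid
    decreased|increased: Normal
    increased|no_function: Intermediate
    normal|normal: Normal
    decreased|normal: Intermediate
    no_function|normal: Intermediate
    decreased|decreased: Intermediate
    decreased|no_function: Poor
    no_function|no_function: Poor
  CYP2B6:
    increased|increased: Ultrarapid
    increased|normal: Rapid
    decreased|increased: Normal
    increased|no_function: Intermediate
    normal|normal: Normal
    decreased|normal: Intermediate
    no_function|normal: Intermediate
    decreased|decreased: Intermediate
    decreased|no_function: Poor
    no_function|no_function: Poor
  SLCO1B1:
    increased|increased: IncreasedFunction
    increased|normal: IncreasedFunction
    normal|normal: NormalFunction
    decreased|increased: NormalFunction
    decreased|normal: DecreasedFunction
    no_function|normal: DecreasedFunction
    increased|no_function: PossiblyDecreasedFunction
    decreased|decreased: PoorFunction
    decreased|no_function: PoorFunction
    no_function|no_function: PoorFunction
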