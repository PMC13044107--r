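# Phenotype -> harmonized recommendation category, per drug context.
# Keys for multi-gene contexts join one phenotype per gene, in the
# context's gene order, with "|". Every in-vocabulary phenotype
# combination must have a cell (validated at load time); Indeterminate and
# missing-gene handling happens upstream of the grid ("Not determined" /
# "No call") and is therefore not encoded here.
#
# Defaults follow the CPIC guideline structure for each drug class:
#  - codeine/tramadol: CYP2D6 ultrarapid and poor metabolizers are steered
#    away from the drug, intermediates are flagged for caution;
#  - citalopram/escitalopram: CYP2C19 ultrarapid/rapid (low exposure) and
#    poor (high exposure) metabolizers get an alternative, intermediates a
#    dose adjustment;
#  - statins: SLCO1B1 decreased transport maps to a context-specific
#    action (alternative statin, caution, or dose adjustment) while poor
#    transporter function always warrants an alternative;
#  - sertraline: two-gene rule — CYP2C19 drives the primary action and a
#    reduced-function CYP2B6 adds a dose adjustment for CYP2C19 normal
#    metabolizers.
version: "1.0"
contexts:
  codeine_tramadol:
    genes: [CYP2D6]
    cells:
      Ultrarapid: Avoid and/or use alternative medication
      Rapid: Use as directed
      Normal: Use as directed
      Intermediate: Use with caution
      Poor: Avoid and/or use alternative medication
  citalopram_escitalopram:
    genes: [CYP2C19]
    cells:
      Ultrarapid: Avoid and/or use alternative medication
      Rapid: Avoid and/or use alternative medication
      Normal: Use as directed
      Intermediate: Adjust dosage
      Poor: Avoid and/or use alternative medication
  lova_pita_simva:
    genes: [SLCO1B1]
    cells:
      IncreasedFunction: Use as directed
      NormalFunction: Use as directed
      DecreasedFunction: Avoid and/or use alternative medication
      PossiblyDecreasedFunction: Avoid and/or use alternative medication
      PoorFunction: Avoid and/or use alternative medication
  pravastatin:
    genes: [SLCO1B1]
    cells:
      IncreasedFunction: Use as directed
      NormalFunction: Use as directed
      DecreasedFunction: Use with caution
      PossiblyDecreasedFunction: Use with caution
      PoorFunction: Avoid and/or use alternative medication
  atorvastatin:
    genes: [SLCO1B1]
    cells:
      IncreasedFunction: Use as directed
      NormalFunction: Use as directed
      DecreasedFunction: Adjust dosage
      PossiblyDecreasedFunction: Adjust dosage
      PoorFunction: Avoid and/or use alternative medication
  sertraline:
    genes: [CYP2B6, CYP2C19]
    cells:
      Ultrarapid|Ultrarapid: Avoid and/or use alternative medication
      Ultrarapid|Rapid: Avoid and/or use alternative medication
      Ultrarapid|Normal: Use as directed
      Ultrarapid|Intermediate: Adjust dosage
      Ultrarapid|Poor: Avoid and/or use alternative medication
      Rapid|Ultrarapid: Avoid and/or use alternative medication
      Rapid|Rapid: Avoid and/or use alternative medication
      Rapid|Normal: Use as directed
      Rapid|Intermediate: Adjust dosage
      Rapid|Poor: Avoid and/or use alternative medication
      Normal|Ultrarapid: Avoid and/or use alternative medication
      Normal|Rapid: Avoid and/or use alternative medication
      Normal|Normal: Use as directed
      Normal|Intermediate: Adjust dosage
      Normal|Poor: Avoid and/or use alternative medication
      Intermediate|Ultrarapid: Avoid and/or use alternative medication
      Intermediate|Rapid: Avoid and/or use alternative medication
      Intermediate|Normal: Adjust dosage
      Intermediate|Intermediate: Adjust dosage
      Intermediate|Poor: Avoid and/or use alternative medication
      Poor|Ultrarapid: Avoid and/or use alternative medication
      Poor|Rapid: Avoid and/or use alternative medication
      Poor|Normal: Adjust dosage
      Poor|Intermediate: Adjust dosage
      Poor|Poor: Avoid and/or use alternative medication
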