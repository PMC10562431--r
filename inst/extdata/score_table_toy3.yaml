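# Toy 3-SNP score table used in examples and tests.
# Each SNP gives 1 fat point for the effect-allele homozygote, 0.5 for the
# heterozygote, and 0 otherwise; the third SNP also scores the carb axis.
version_tag: TOY
fat_threshold: 2
carb_threshold: 1
panel:
  - rsid: rs0000001
    chromosome: "1"
    alleles: [A, G]
    points:
      GG: {fat: 0, carb: 0}
      AG: {fat: 0.5, carb: 0}
      AA: {fat: 1, carb: 0}
  - rsid: rs0000002
    chromosome: "2"
    alleles: [C, T]
    points:
      TT: {fat: 0, carb: 0}
      CT: {fat: 0.5, carb: 0}
      CC: {fat: 1, carb: 0}
  - rsid: rs0000003
    chromosome: "3"
    alleles: [G, T]
    points:
      TT: {fat: 0, carb: 1}
      GT: {fat: 0.5, carb: 0.5}
      GG: {fat: 1, carb: 0}
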