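# Synthetic 10-SNP diet-responder score table.
#
# The panel lists ten variants reported in the nutrigenomics literature as
# modifying weight-loss response to high-fat vs. high-carbohydrate diets.
# The POINT VALUES AND THRESHOLDS BELOW ARE SYNTHETIC: they are this
# package's own construction, chosen (together with the default effect-
# allele frequencies in simulation_config()) so that the population class
# probabilities are approximately 41% fat-responder, 20% carbohydrate-
# responder, and 39% neither-or-both. They are suitable for simulation and
# pipeline testing, not for classifying real people.
#
# Alleles are listed effect allele first. Genotype keys give per-genotype
# points on the fat and carbohydrate responsiveness axes.
version_tag: UPDATED_10SNP
fat_threshold: 4
carb_threshold: 5
panel:
  - rsid: rs5082
    gene: APOA2
    chromosome: "1"
    alleles: [C, T]
    points:
      TT: {fat: 0, carb: 0}
      CT: {fat: 1, carb: 0}
      CC: {fat: 2, carb: 0}
  - rsid: rs894160
    gene: PLIN1
    chromosome: "15"
    alleles: [T, C]
    points:
      CC: {fat: 0, carb: 0}
      CT: {fat: 1, carb: 0}
      TT: {fat: 2, carb: 0}
  - rsid: rs662799
    gene: APOA5
    chromosome: "11"
    alleles: [G, A]
    points:
      AA: {fat: 0, carb: 0}
      AG: {fat: 1, carb: 0}
      GG: {fat: 2, carb: 0}
  - rsid: rs1801282
    gene: PPARG
    chromosome: "3"
    alleles: [G, C]
    points:
      CC: {fat: 0, carb: 0}
      CG: {fat: 1, carb: 0}
      GG: {fat: 2, carb: 0}
  - rsid: rs838147
    gene: FGF21
    chromosome: "19"
    alleles: [C, A]
    points:
      AA: {fat: 0, carb: 2}
      AC: {fat: 1, carb: 1}
      CC: {fat: 2, carb: 0}
  - rsid: rs12255372
    gene: TCF7L2
    chromosome: "10"
    alleles: [T, G]
    points:
      GG: {fat: 2, carb: 0}
      GT: {fat: 1, carb: 1}
      TT: {fat: 0, carb: 2}
  - rsid: rs9939609
    gene: FTO
    chromosome: "16"
    alleles: [A, T]
    points:
      TT: {fat: 0, carb: 0}
      AT: {fat: 0, carb: 1}
      AA: {fat: 0, carb: 2}
  - rsid: rs2943641
    gene: IRS1
    chromosome: "2"
    alleles: [T, C]
    points:
      CC: {fat: 0, carb: 0}
      CT: {fat: 0, carb: 1}
      TT: {fat: 0, carb: 2}
  - rsid: rs10423928
    gene: GIPR
    chromosome: "19"
    alleles: [A, T]
    points:
      TT: {fat: 0, carb: 0}
      AT: {fat: 0, carb: 1}
      AA: {fat: 0, carb: 2}
  - rsid: rs1478290
    gene: GYS2
    chromosome: "12"
    alleles: [T, G]
    points:
      GG: {fat: 0, carb: 0}
      GT: {fat: 0, carb: 1}
      TT: {fat: 0, carb: 2}
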