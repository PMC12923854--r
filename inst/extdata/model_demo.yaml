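# SYNTHETIC demonstration model.
# The published HIrisPlex-S coefficients are not reproduced here; these
# numbers were invented for the test-suite and examples so that genotype
# changes move the trait probabilities in biologically sensible directions
# (derived pigmentation alleles push towards darker categories, MC1R
# loss-of-function dosage pushes towards red hair). Do not use for inference.
model: demo-synthetic-1
groups:
  eye:
    reference: blue
    categories:
      intermediate:
        intercept: 0.5
        coefficients:
          rs12913832_T: 1.2
          rs1800407_A: 0.4
          rs12203592_T: 0.3
      brown:
        intercept: 1.0
        coefficients:
          rs12913832_T: 2.6
          rs16891982_C: 0.9
          rs1393350_A: -0.5
          rs12896399_T: 0.3
  hair_colour:
    reference: blond
    categories:
      brown:
        intercept: 0.3
        coefficients:
          rs12913832_T: 0.8
          rs683_G: 0.5
          rs12821256_G: -0.8
      red:
        intercept: -4.0
        coefficients:
          rs312262906_A: 3.0
          rs11547464_A: 2.0
          rs885479_T: 1.0
          rs1805008_T: 2.0
          rs1805005_T: 1.0
          rs1805006_A: 2.5
          rs1805007_T: 2.5
          rs1805009_C: 2.5
          rs201326893_A: 2.5
          rs2228479_A: 0.8
          rs1110400_C: 1.5
      black:
        intercept: -0.5
        coefficients:
          rs12913832_T: 1.5
          rs16891982_C: 1.2
          rs2402130_G: 0.4
  hair_shade:
    reference: light
    categories:
      dark:
        intercept: -0.3
        coefficients:
          rs12913832_T: 1.0
          rs16891982_C: 0.8
          rs683_G: 0.4
          rs6059655_T: 0.3
  skin:
    reference: very_pale
    categories:
      pale:
        intercept: 1.2
        coefficients:
          rs1426654_G: 0.5
          rs16891982_C: 0.4
      intermediate:
        intercept: 0.6
        coefficients:
          rs1426654_G: 1.3
          rs16891982_C: 1.0
          rs1545397_T: 0.4
          rs1042602_A: -0.3
      dark:
        intercept: -1.0
        coefficients:
          rs1426654_G: 2.2
          rs16891982_C: 1.8
          rs6119471_C: 0.8
          rs10756819_A: 0.4
      dark_black:
        intercept: -2.5
        coefficients:
          rs1426654_G: 3.0
          rs16891982_C: 2.4
          rs6119471_C: 1.4
          rs3114908_T: 0.5
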