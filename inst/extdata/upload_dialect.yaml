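# Upload-file dialect for the probe allele-count CSV.
# The exact header spelling used by the hosted batch service is not under our
# control; it is isolated here so it can be corrected without code changes.
dialect: hisplexr-upload-1
sample_column: sampleid
na_token: "NA"
probe_columns:
  - rs312262906_A
  - rs11547464_A
  - rs885479_T
  - rs1805008_T
  - rs1805005_T
  - rs1805006_A
  - rs1805007_T
  - rs1805009_C
  - rs201326893_A
  - rs2228479_A
  - rs1110400_C
  - rs28777_C
  - rs16891982_C
  - rs12821256_G
  - rs4959270_A
  - rs12203592_T
  - rs1042602_A
  - rs1800407_A
  - rs2402130_G
  - rs12913832_T
  - rs2378249_G
  - rs12896399_T
  - rs1393350_A
  - rs683_G
  - rs3114908_T
  - rs1800414_C
  - rs10756819_A
  - rs2238289_G
  - rs17128291_G
  - rs6497292_G
  - rs1129038_G
  - rs1667394_G
  - rs1126809_A
  - rs1470608_A
  - rs1426654_G
  - rs6119471_C
  - rs1545397_T
  - rs6059655_T
  - rs12441727_A
  - rs3212355_T
  - rs8051733_C
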