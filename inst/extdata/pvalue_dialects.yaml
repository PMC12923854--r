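# Column-name dialects for the 14-p-value table.
# "native" is what compute_pvalues() writes; "webtool" mirrors the batch
# result file downloaded from the hosted phenotyping service, so that file
# can be fed to classify_all() unchanged. Order matters and is fixed.
native:
  sample: sampleid
  columns:
    - p_eye_blue
    - p_eye_intermediate
    - p_eye_brown
    - p_hair_blond
    - p_hair_brown
    - p_hair_red
    - p_hair_black
    - p_shade_light
    - p_shade_dark
    - p_skin_very_pale
    - p_skin_pale
    - p_skin_intermediate
    - p_skin_dark
    - p_skin_dark_black
webtool:
  sample: SampleID
  columns:
    - PBlueEye
    - PIntermediateEye
    - PBrownEye
    - PBlondHair
    - PBrownHair
    - PRedHair
    - PBlackHair
    - PLightHair
    - PDarkHair
    - PVeryPaleSkin
    - PPaleSkin
    - PIntermediateSkin
    - PDarkSkin
    - PDarkBlackSkin
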