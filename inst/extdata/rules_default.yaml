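# Default classification rule set.
# The hair and skin heuristics approximate the published HIrisPlex-S user
# manual's decision tree; the exact manual constants are not reproduced here,
# so users transcribing the manual can replace this file without code
# changes. Category orders run light -> dark and drive the darker-tone
# tie-breaking. Skin modifiers are ratio-based (runner-up probability over
# base-tone probability) so the light/dark modifier is invariant under
# renormalisation of the five skin p-values.
ruleset: hisplexr-default-1
eye:
  categories: [blue, intermediate, brown]
hair:
  colour_categories: [blond, brown, red, black]
  shade_categories: [light, dark]
  # P(dark shade) cut points refining the base colour into the 8-way vocabulary
  dark_shade_low: 0.3
  dark_shade_high: 0.7
skin:
  base_categories: [very_pale, pale, intermediate, dark, dark_black]
  # an adjacent tone whose probability is at least this fraction of the base
  # tone's probability attaches a lighter/darker modifier
  modifier_ratio: 0.5
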