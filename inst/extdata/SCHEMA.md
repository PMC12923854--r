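# File schemas for the shipped fixtures

## markers_hisplex_s.tsv — the 41-marker HIrisPlex-S catalog

Tab-separated, one row per marker, header required. The catalog is data, not
code: coordinates, strand and counted allele were curated from the published
HIrisPlex-S assay literature, and corrections belong in this file, never in R
sources.

| column                 | meaning                                                              |
|------------------------|----------------------------------------------------------------------|
| rsid                   | dbSNP identifier, unique                                             |
| chrom                  | chromosome (plain dialect, e.g. `16`; `chr16` is derived at load)    |
| pos_GRCh37             | 1-based position on GRCh37/hg19                                      |
| pos_GRCh38             | 1-based position on GRCh38/hg38                                      |
| ref                    | reference allele on the forward strand of the build                  |
| alt                    | alternate allele on the forward strand (`AA` for the dupA insertion) |
| probe_strand           | `forward` or `reverse`: strand the assay probe was designed on       |
| counted_allele         | allele symbol the probe reports, written on the probe strand         |
| variant_class          | `SNP` or `single-base-duplication`                                   |
| global_maf             | global minor allele frequency, in [0, 0.5]                           |
| trait_tags             | comma-separated subset of `eye,hair,skin,mc1r`                       |
| may_be_absent_GRCh38   | TRUE when GRCh38-based joint call sets are known to omit the site    |

Invariants enforced at load: exactly 41 rows; unique rsids; unique
(chrom, pos) per build; SNP rows have single-base ref != alt; probe_strand in
{forward, reverse}; for a reverse-strand SNP the reverse complement of
counted_allele must equal ref or alt; exactly 11 rows carry the `mc1r` tag.

## chrom_lengths.tsv — chromosome sizes

Tab-separated: `build` (GRCh37 or GRCh38), `chrom` (plain dialect), `length`
(bp, > 0). hg19/hg38 share lengths with GRCh37/GRCh38; only the chromosome
naming dialect differs.

## model_demo.yaml — synthetic demonstration model

Multinomial-logistic coefficients for the four trait groups. THIS IS A
SYNTHETIC DEMO MODEL used by the test-suite and examples; it is not the
published HIrisPlex-S model. Users holding the published coefficients supply
their own file with the same layout:

```yaml
model: <name>
groups:
  <group>:              # eye, hair_colour, hair_shade, skin
    reference: <category with linear predictor fixed at 0>
    categories:
      <category>:
        intercept: <number>
        coefficients:
          <probe>: <number>    # probe = "<rsid>_<counted allele>"
```

## rules_default.yaml — classifier rule set

Threshold constants for the hair and skin decision heuristics, plus the
light-to-dark category orders used for tie-breaking. See the package vignette
for the exact decision logic each constant feeds.

## upload_dialect.yaml — probe-count upload file dialect

The header spelling and missing-data token of the probe-count CSV expected by
the HIrisPlex-S batch upload. The probe column order must match the catalog
order; the loader cross-checks the two.
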