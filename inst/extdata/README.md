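# Packaged data files

- `column_dictionary.json` — the cohort CSV schema: item columns with their
  scale ranges, demographic level sets (both age-band codings), and the
  suicidal-behavior status levels.
- `default_constraints.json` — an *illustrative* expert constraint set for
  structure search (sociodemographics exogenous, the group node a sink).
  It is a plausible domain prior shipped as editable data, not a published
  expert graph; replace it with your own whitelist/blacklist for real use.
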