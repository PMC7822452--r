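Optional external validation records (not redistributable; fetch once):

- `BK013136.fasta` — the deposited mitovirus genome (GenBank TPA); enables
  the deposited-genome acceptance check.
- `uga_panel/*.gb` plus `uga_panel/expected.tsv` (columns: accession,
  uga_trp_percent) — GenBank records for the published UGA(Trp) panel;
  enables the panel acceptance check.
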