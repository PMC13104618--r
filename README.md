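# trantyper

Surveying and typing **TraN**, the outer-membrane mating-pair-stabilization
protein of F-type (MPF<sub>F</sub>) conjugation systems, across plasmid
corpora — and predicting what that typing implies for receptor dependency
and recipient host range.

## Why

Conjugative IncF, IncA/C and IncH plasmids are major vehicles of
antimicrobial-resistance genes (notably *bla*<sub>NDM-1</sub>). After pilus
retraction, efficient DNA transfer requires mating pair stabilization:
TraN in the donor outer membrane binds an outer-membrane protein (OMP) in
the recipient. TraN comes in size/structure classes with distinct host
preferences:

| class | length (aa) | typical replicons | receptor |
|---|---|---|---|
| TraN_S | 550–660 | IncF | OmpW / OmpK36 / OmpA / OmpF (isotypes α/β/γ/δ) |
| TraN_M | 880–950 | IncA/C, IncA/C2 | unknown |
| TraN_L | 1,050–1,070 | IncH | OmpA |
| TraN_V | 891 (two tips) | *A. baumannii* plasmids | unknown (tip T2 works only toward *A. baumannii*) |

Each protein is a conserved membrane-embedded **base** plus a variable
distal **tip** that confers species specificity. `trantyper` implements the
desk-scale analysis around this typology for surveillance work:

1. **Extraction** — parse GenBank plasmid records and pull every CDS
   annotated `traN`/`TraN`/`trhN`/`TrhN` (whole-token, case-sensitive;
   substring matching is an explicit option), translating with the
   bacterial genetic code (table 11) where deposited records lack a
   `/translation`.
2. **Pairwise similarity** — exact global Needleman–Wunsch alignment with
   affine gaps (BLOSUM62, gap open 10 / extend 1, end gaps penalized);
   percent similarity = identities / alignment columns, so large length
   differences are penalized. Exported as PHYLIP or long-format TSV.
3. **Typing** — size-class bins plus nearest-reference subclade assignment
   (TraN_Malpha/Mbeta, TraN_Lalpha/Lbeta/Lgamma, TraN_V) at a ≥30%
   similarity threshold, with the reference tip span projected onto each
   query through the alignment. TraN_V is only ever confirmed by
   similarity — its 891 aa length sits inside the M bin.
4. **Trees** — neighbor joining on `d = (100 − similarity)/100` with
   deterministic tie-breaks, midpoint rooting, Newick export.
5. **Survey statistics** — per-plasmid copy-number tables, size-class
   proportions, trait (e.g. carbapenemase) and host-taxon associations per
   family/subclade; log10 conjugation-frequency arithmetic with an explicit
   below-detection sentinel.
6. **Host-range prediction** — a curated, provenance-tagged evidence table
   mapping each subclade to its receptor and per-recipient efficiency
   tiers; nothing is extrapolated beyond curated evidence.
7. **Synthetic corpora** — a fully seeded generator (quota and random
   modes) producing GenBank records, metadata and ground truth, so the
   whole pipeline is testable offline.

## Worked example

```r
library(trantyper)

spec <- corpus_spec(n_plasmids = 12, copy_number = c("0" = 1, "1" = 11),
                    class_mix = c(S = 4, Malpha = 2, Mbeta = 2,
                                  Lalpha = 2, Lgamma = 1, V = 0),
                    substitution_rate = 0.15, seed = 42)
corpus <- build_corpus(spec)
tran   <- extract_tran_corpus(corpus$records)
refs   <- corpus$references[names(reference_profiles())]
typing <- type_corpus(tran, refs, map_tips = TRUE)
typing[1:4, c("record_id", "length", "size_class", "family",
              "subclade", "identity", "tip_start", "tip_end")]
#>   record_id length size_class family    subclade identity tip_start tip_end
#> 1   p0001|1    605          S      S        <NA> 15.47492        NA      NA
#> 2   p0003|1    605          S      S        <NA> 15.96091        NA      NA
#> 3   p0004|1    605          S      S        <NA> 16.04167        NA      NA
#> 4   p0005|1    912          M      M TraN_Malpha 85.41667       230     360
```

Row 4 is a medium-class protein 85.4% identical to the RA1-type reference;
its receptor-binding tip maps to query residues 230–360. The short-bin
proteins stay family `S` (their isotypes need TraN_S profiles, supplied by
the user). Corpus-level summary and a host-range prediction:

```r
survey_report(corpus$records, tran, typing, corpus$metadata)
#> <SurveyReport> 12 plasmids, 11 TraN proteins extracted
#> copy number (% of plasmids):
#>   category count percent
#> 1        0     1     8.3
#> 2        1    11    91.7
#> 3      2-3     0     0.0
#> 4       >3     0     0.0
#> size classes (% of extracted proteins):
#>   size_class count percent
#> 1          S     4    36.4
#> 2          M     4    36.4
#> 3          L     3    27.3
#> 4          V     0     0.0
#> 5      other     0     0.0

i <- which(typing$subclade == "TraN_Lalpha")[1]
predict_host_range(typing[i, ])
#> <HostRangePrediction> TraN_Lalpha - receptor: OmpA
#>   high : Klebsiella pneumoniae, enteropathogenic E. coli (EPEC), Escherichia coli MG1655
#>   reduced : Enterobacter cloacae, Shigella sonnei
#>   very_low : Salmonella Enteritidis, Citrobacter freundii
```

A thin command-line front end over the same functions ships in
`inst/cli/trantyper.R` (`simulate`, `extract`, `similarity`, `type`,
`tree`, `survey`, `predict`).

## Scope

Structure prediction, wet-lab assay statistics, and external
replicon/AMR/PTU callers are out of scope; their outputs are consumed as
plasmid metadata (`read_metadata()`). Maximum-likelihood tree inference is
deliberately replaced by the self-contained neighbor-joining stand-in —
the exported Newick files feed external ML tools directly if parity is
needed.
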