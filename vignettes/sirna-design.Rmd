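---
title: "Designing functional siRNAs with reduced seed-dependent off-target activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing functional siRNAs with reduced seed-dependent off-target activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnadesign)
library(dplyr)
```

## The problem

RNA interference in mammalian cells is directed by 21-nt siRNA duplexes with
2-nt 3′ overhangs. Two practical difficulties dominate siRNA selection.
First, silencing efficacy varies enormously with sequence: only duplexes
whose guide (antisense) strand is preferentially loaded into the RISC are
strongly functional, and that loading is governed by the thermodynamic
asymmetry of the duplex ends. Second, even a perfectly specific guide can
repress hundreds of unintended transcripts through miRNA-like recognition:
a perfect Watson–Crick match between the guide *seed* (positions 2–8,
numbered 1-based from the guide 5′ end) and a heptamer in a transcript's
3′-UTR is sufficient to trigger repression, and the strength of this
seed-dependent off-target effect tracks the thermodynamic stability of the
7-bp seed–target duplex.

`sirnadesign` operationalizes both constraints. A candidate guide is
accepted only if it simultaneously satisfies five conditions:

1. A or U at guide position 1;
2. at least four A/U residues among guide positions 1–7 (A/U ≥ 57%,
   since ⌊100·4/7⌋ = 57);
3. G or C at guide position 19;
4. no run of consecutive G/C residues longer than 9 nt;
5. seed–target duplex melting temperature $T_m \le$ 21.5 °C.

Conditions 1–3 encode the terminal asymmetry that selects the guide strand
into the RISC (an A/U-rich, weakly paired guide 5′ end and a G/C-clamped
3′ end); condition 4 avoids duplexes whose Ago2-cleaved passenger fragments
cannot dissociate; condition 5 keeps the seed–target duplex weak enough to
make the guide a poor inducer of seed-dependent off-target repression.

## The thermodynamic model

The seed–target duplex is modeled as the fully complementary 7-bp helix
formed by guide positions 2–8. Its melting temperature is computed with the
two-state nearest-neighbor model,

$$
T_m\,[^\circ\mathrm{C}] \;=\;
\frac{1000\,\Delta H^\circ}{\Delta S^\circ + R \ln (C_T/4)}
\;-\; 273.15 \;+\; 16.6 \log_{10} [\mathrm{Na^+}],
$$

where $\Delta H^\circ$ (kcal/mol) and $\Delta S^\circ$ (cal/(mol·K)) sum
the six interior dinucleotide stacks of the helix plus the helix initiation
terms, $R = 1.987$ cal/(mol·K), $C_T$ is the total strand concentration and
$[\mathrm{Na^+}]$ the monovalent salt concentration. The shipped parameter
table (`inst/extdata/freier1986_rna_nn.tsv`) is the RNA/RNA set of Freier
et al. (1986) — 16 dinucleotide stacks with an initiation entropy of
−10.8 cal/(mol·K) and zero initiation enthalpy — evaluated at
$C_T = 100\ \mu M$ and $[\mathrm{Na^+}] = 100$ mM, the conditions under
which the 21.5 °C benchmark separating strong from weak off-target inducers
was established. The table is duplex-symmetric (a stack carries the same
parameters as its reverse complement read from the opposite strand), which
the loader verifies and which makes `seed_tm(x) == seed_tm(revcomp(x))`
hold exactly.

Three modeling choices deserve emphasis:

* **The seed is treated in isolation.** Dangling ends and flanking target
  context are ignored; seed stability is a property of the 7-mer alone.
  This matches how the stability–off-target relationship was established
  (reporter constructs varying only the 7-nt seed) and keeps the statistic
  over seed space well defined.
* **Thresholds are inclusive.** "$T_m \le 21.5$" admits a candidate whose
  Tm equals the threshold exactly; symmetrically, the off-target classifier
  calls a guide a *strong* inducer when its seed Tm is **at or above** the
  benchmark. The two readings meet at the benchmark itself, where the
  strong call is the conservative one for an off-target audit.
* **Two related thresholds coexist.** The design filter defaults to
  21.5 °C (`design_config()`), while the seed-space fraction is
  conventionally quoted at 21 °C (`seed_space()`'s default flag). Both are
  plain arguments; neither is hard-coded.

With the shipped table, enumerating all $4^7 = 16{,}384$ seeds shows how
constrained the usable seed space is — and that mean Tm rises strictly with
seed GC content:

```{r seedspace}
params <- nn_params()
ss <- seed_space(params, threshold = 21)
nrow(ss)
100 * mean(ss$below_threshold)          # % of seed space at or below 21 degC
100 * fraction_below(21.5, params)      # at the design threshold
ss |>
  mutate(gc = stringr::str_count(seed, "[GC]")) |>
  group_by(gc) |>
  summarise(mean_tm = mean(tm_celsius), n = n())
```

So roughly a quarter of seed space is weak enough for off-target-conscious
design under this parameterization. `plot_seed_space(ss)` draws the full
distribution.

## From mRNA to ranked candidates

Candidates are enumerated by sliding a 23-nt window along the target mRNA.
For a window $w[1..23]$ (1-based inclusive), the passenger (sense) strand
is $w[3..23]$ and the guide is the reverse complement of $w[1..21]$: a
19-bp duplex core with 2-nt 3′ overhangs on both strands, the standard
duplex geometry. Guide position 1 pairs $w[21]$; the seed pairs
$w[14..20]$.

```{r design}
mrna <- synthetic_mrna(300, gc_fraction = 0.45, seed = 5, id = "demo")
fit <- sirna_design(mrna, design_config(), nn_params())
glance(fit)
tidy(fit) |> select(window_start, guide, seed_tm_celsius, all_pass) |> head(3)
```

Because the five conditions are pure pass/fail, no efficacy score exists to
sort by. The package still needs a deterministic presentation order, and
orders passing candidates by seed Tm ascending (weakest off-target inducer
first), with ties broken by A/U count at positions 1–7 descending, then by
target id and window start. This ordering is the package's own choice; it
is presentation only and never changes which candidates pass. Overlapping
passing candidates are all reported — no spacing constraint is imposed —
and `--region`/`restrict_to_region` lets the user confine designs to, say,
the ORF, a choice the method itself does not dictate.

Ambiguous residues (IUPAC codes such as N) are rejected at normalization by
default: the rules and the Tm model are undefined on them, and failing
loudly beats guessing. With `permissive = TRUE` at read time and
`skip_ambiguous_windows = TRUE` in the config, windows containing such
residues are skipped and counted instead.

## Off-target auditing

`find_seed_matches()` scans a sequence collection (typically 3′-UTRs, sense
strand) for every occurrence of the reverse complement of the guide seed.
Matching is exact Watson–Crick on the heptamer — no G:U wobble, no
position-1 conventions from the miRNA target-prediction literature — since
the 7-nt perfect seed match is what defines the off-target trigger here.
All overlapping occurrences are counted: each is a potential binding site
and no de-duplication rule is part of the model. `offtarget_summary()`
aggregates counts per sequence and classifies the guide as a strong or weak
off-target inducer from its seed Tm alone; the class deliberately does not
depend on how many sites the supplied collection happens to contain, and no
attempt is made to predict per-transcript repression magnitudes — the model
claims a stability-determined dichotomy, and that is all the class encodes.

```{r offtarget}
utrs <- rna_tbl(c(strrep("U", 30), "ACGUACGUACGUACGUACGU"),
                c("utr1", "utr2"))
aud <- offtarget_summary(utrs, "GAAAAAAAUCGUACGAUCGUA")
glance(aud)
```

## The synthetic-mRNA generator

`synthetic_mrna()` draws residues i.i.d. with
$P(G) = P(C) = \mathrm{gc}/2$ and $P(A) = P(U) = (1-\mathrm{gc})/2$,
bit-reproducibly for a fixed seed and without touching the caller's RNG
state. The default GC fraction of 0.5 approximates typical mammalian
coding sequence; the test fixtures mostly use 0.45, on the AU-rich side of
real transcripts, which keeps all five rules exercised in both directions
on short sequences. What the generator emulates is composition only: real
mRNAs have local composition structure (CpG islands, AU-rich 3′-UTR
elements, codon bias) and secondary structure that i.i.d. sampling cannot
produce. Passing tests on synthetic input therefore demonstrate the
correctness of the enumeration, rules, thermodynamics and scanning — not
that designed siRNAs will silence a given real transcript, which
additionally depends on target accessibility and cellular context that are
outside this package's model.

## Numerical and testing choices

* Tm is evaluated in double precision directly from the summed stack
  parameters; there is no iteration and no tolerance beyond floating-point
  arithmetic. Strand symmetry holds exactly (the same stack multiset is
  summed), not merely to a tolerance.
* Validation is strict and early: sequences are normalized once (T→U,
  case-folded) with 1-based error positions; guides must be exactly 21 nt,
  seeds exactly 7 nt.
* The test suite pins `seed_tm` to hand-summed values for homopolymer and
  mixed seeds, checks every rule against naive re-implementations, checks
  the designer against exhaustive window re-evaluation on mRNAs of 200–400
  nt, and checks the scanner against a naive substring scan on UTRs up to
  10 kb — sizes at which the naive oracles are themselves trivially
  auditable.
* Degenerate inputs have defined behavior: mRNAs shorter than 23 nt yield
  zero candidates with a warning; an empty UTR collection yields a
  classified summary with zero matches; the empty string is its own
  reverse complement.

## Known limitations

* The Tm model covers fully complementary 7-bp RNA/RNA duplexes only — no
  mismatches, internal loops, dangling ends, or alternative salt
  corrections. That is the regime in which the 21.5 °C benchmark is
  defined.
* Off-target auditing is seed-complementarity only. It does not perform
  mismatch-tolerant guide-wide alignment (BLAST/Smith–Waterman-style
  specificity screening) and so complements, rather than replaces, a
  transcriptome-wide specificity search.
* The five conditions are qualitative gates; the package intentionally
  provides no quantitative efficacy regression.
* Nothing in the package models target-site accessibility or chemical
  modification strategies.
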