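---
title: "Methods: discovering group II intron retroelements offline"
author: "intronminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering group II intron retroelements offline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Group II introns are bacterial retroelements made of a self-splicing ribozyme
(~500-800 nt, domains DI-DVI) and an intron-encoded protein (IEP) carrying a
reverse transcriptase (RT) with subdomains 0-7, the thumb domain X, and an
optional endonuclease En. The IEP is easy to find by translated homology
search; the ribozyme boundaries are not, because the only universal signals
are the short termini consensus GUGYG ... AY. Most intron copies in genomes
are also truncated or otherwise dead. A discovery pipeline therefore has to
(i) cast a wide net with a permissive protein search, then (ii) strip away
everything that is not a live, full-length group II intron, and finally
(iii) collapse near-identical copies into one representative each.

`intronminer` implements that pipeline as an eight-stage state machine:

0. **collect** - translated search of query IEPs against genomic records,
   pooling of overlapping hits into unique loci, taxonomy bucketing, and
   extraction of oriented candidate windows with 3 kb flanks;
1. **filter_rts** - vote-based screening against a categorized RT set
   (retrons, CRISPR-associated RTs, DGRs, ...): a candidate proceeds only if
   the top three matches are group II introns;
2. **find_class** - class assignment (ML, CL, A-F, unclassified, undefined)
   by top-three agreement against the curated intron IEP set, recording the
   closest curated relative;
3. **find_orf_domains** - per-domain presence inventory against a class
   reference IEP with one proxy residue per domain;
4. **find_orf** - intactness judgment (single uninterrupted alignment to the
   closest relative) and IEP emission with start-codon selection;
5. **find_boundaries** - class-specific 5'/3' boundary profile scanning with
   two scorers;
6. **generate_rna** - resolution of a unique, ordered, plausible boundary
   pair and emission of the intron sequence;
7. **group** - ML-distance clustering of the domain 0-to-X region at the
   0.061 substitutions/site threshold (~95% identity) and prototype
   selection, one per group plus one per species within a group.

Every stage only shrinks the retained set; set-aside candidates keep a
labelled reason, giving a complete storage-folder audit trail.

## The search engine and its statistics

Queries are protein; subjects are DNA searched in all six frames (bacterial
code, table 11). The pairwise core is an affine-gap Smith-Waterman
(BLOSUM62, gap open 11, extend 1) implemented in C++; on this machine it
runs at a few hundred million DP cells per second, which is what makes the
desk-scale corpus tractable without heuristic seeding. Significance uses
Karlin-Altschul statistics, `E = K * m * n * exp(-lambda * S)` with the
standard gapped parameters lambda = 0.267, K = 0.041, where `m` is the query
length and `n` the subject frame length in residues. The default search
cutoff is `E <= 1e-20`, deliberately permissive so that distant relatives
and fragments enter the pipeline and are removed by the later, more specific
stages rather than by search stringency. A property test checks the
calibration empirically: on shuffled subjects the observed tail
`P(bit >= s)` stays within a factor of three of the Karlin-Altschul
prediction.

Overlapping hits from different queries on the same strand are merged by
interval union (one nucleotide of overlap suffices; adjacent intervals stay
separate). Windows are cut with 3 kb of flanking sequence per side,
truncated at record ends, and oriented so the IEP is on the forward strand;
a coordinate map back to the source record is kept and verified by a
round-trip property test.

## Screening rules

The RT verdict counts group II references among the top three matches
(ranked by E-value, ties by raw score then reference id, so database order
never matters): 3 gives `probable`, 1-2 `possible`, 0 `non_group_II`. Only
probable candidates proceed by default; the vote threshold and the E-value
ceiling are configuration, since the right stringency depends on the
reference set at hand. With fewer than three scoring references the rule applies
to the available ranks, so `probable` is unreachable - the conservative
reading.

Class assignment uses the same ranking against the curated IEP set: top
three in one defined class assigns that class; three curated
"unclassified" hits give `unclassified`; any disagreement gives
`undefined`. CL1/CL2 reference subclasses both count as class CL, with the
best match's subclass kept as metadata. Undefined and unclassified
candidates stay in the main track (they are later scanned with the boundary
profiles of all classes); only candidates with no curated match at all are
set aside.

## Domains, intactness, and the IEP start

Each class reference IEP carries one conserved residue per domain
(0-7, X, optionally En) as a proxy; a domain is counted present in each
distinct alignment whose aligned columns include the proxy position - the
candidate residue need not be identical. Distinctness is judged on window
coordinates so that twintrons (nested intron copies) count each ORF copy and
land in `extra domains`. Expected domains are per-reference metadata: class
C references have no En, so its absence is never a false `missing`.

Intactness demands a single HSP against the closest curated relative, no
stop codon in the aligned frame, no gap run longer than 2 codons (a strict
no-gap rule would reject natural one-codon indels; the allowance is
configuration), and coverage of at least 95% of the relative's domain
0-to-X span. Frameshifts split the alignment into HSPs in different frames;
a second ORF copy elsewhere in the window re-covering the same relative
residues is set aside as "multiple ORF locations", quarantining
twintron-bearing windows where per-window analysis would go wrong.

The IEP start codon is scanned among in-frame ATG/GTG/TTG within 45 nt of
the position aligning to the relative's start. Each candidate start scores
an alignment-consistency term (1 at the exact aligned position, minus 0.3
per codon of offset), a start-codon bonus (ATG 0.5, GTG 0.2, TTG 0), and a
Shine-Dalgarno term: the best position-weight-matrix score of the AGGAGG
core (consensus probability 0.7, log2-odds against uniform background,
floored at 0) in a 5-13 nt spacer upstream. The scan half-width and spacer
range are typical bacterial values and are configuration. The emitted
protein starts with M regardless of the start codon, as translated.

## Boundary profiles and the two scorers

Per class and side, a profile is estimated from an aligned block of
boundary training sequences: per-column base frequencies with a Laplace
pseudocount of 1, expressed as log-odds against uniform background. The
packaged generator trains 5' blocks anchored at the intron's first
nucleotide and 3' blocks at its last, so a profile match position *is* the
boundary call.

Two algorithms score every window offset over the same parameterization: a
best-path (Viterbi-style) score and a log-sum-over-paths (forward-style)
score, over alignments of all profile columns with banded insertions and
deletions (flat penalties in nats). The forward score dominates the best
path by construction, and whichever scorer's calibrated z-score is higher is
kept per offset - the "run both, keep the best score" behaviour. Both
scorers are calibrated on 1000 seeded random windows: the mean and standard
deviation of the per-window maximum score are recorded, together with a
Gumbel scale `beta = sd * sqrt(6) / pi`, so the calibration transfers to
windows of other lengths by shifting the expected maximum with
`beta * log(n/n0)`. Tier thresholds on that z-score are high >= 6,
medium >= 4, low >= 2.5 (configuration; there is no field-standard
definition of these confidence bins).

Profile lengths default to 30 columns (5') and 25 columns (3'). This is a
deliberate design choice: a motif of 10-15 informative columns carries at
most ~13-19 nats of log-odds, while the maximum of the background score over
an 8 kb window sits only ~6 nats below that with a Gumbel scale near 1.3 -
arithmetic that caps the achievable z-score around 4-5 and makes a
high-confidence tier meaningless. The canonical terminal consensus strings
(e.g. class C 5' GUNYGCCNRGCAUGG and 3' CCUACYCGAU) are therefore treated as
the outermost core of longer class-conserved boundary blocks: the generator
keeps them verbatim at the terminus and extends them inward with generated
conserved columns - the situation with real boundary profiles, which are
estimated from full boundary alignments rather than consensus snippets.
Profile lengths remain configuration for users supplying their own training
alignments.

Resolution requires exactly one plausible boundary per side: tier at or
above the floor (high by default), 5' upstream of the ORF start, 3'
downstream of the ORF end, and an implied intron length within
[400, 8000] nt - generous brackets around known intron sizes, with the ORF
strictly inside. Anything else is `ambiguous`, with reasons. A flag admits
the single best lower-tier candidate on a side that has no high-tier one,
a materially more sensitive setting on hard classes; when the two scorers'
top positions disagree, both scores are surfaced and the higher calibrated
score ranks.

## Redundancy grouping

For each class, the IEP region from the domain-0 proxy to the domain-X
proxy is excised (via the reference alignment, extrapolating through local
alignment clipping), aligned progressively with mafft, and pairwise
distances are computed as maximum-likelihood branch lengths under the JTT
model - a PROTDIST-equivalent, implemented as a 1-D likelihood optimization
over the eigendecomposition of the JTT rate matrix (rates as shipped with
phangorn). Columns with a gap in either sequence are excluded pairwise.
Members closer than 0.061 substitutions/site join the same group by single
linkage - the empirically established cutoff for ~95% identity, kept
verbatim even though a 95%-identical 400-residue pair sits nearer 0.052
under JTT, so the threshold has a comfortable margin. Tests cross-check the distance
against both an independent grid-search oracle and `phangorn::dist.ml`.

Each group gets one primary prototype - the longest intact intron, ties
broken by candidate id (a deterministic criterion, exposed in reports) - plus one prototype per
distinct species, so cross-species redundancy remains visible in the final
set, in the classic two-folder output layout (full set and prototype set).

## The synthetic fixture generator

Everything above is exercised offline against a deterministic generator
(`fixture_spec()`, `make_reference_bundle()`, `plant_genome()`). Per class
it builds an ancestral IEP (420-600 residues), curated relatives at 90%
identity, a reference IEP with evenly spaced domain proxies, and boundary
training blocks sampled from the class consensus. Planted elements are
assembled as 5' motif + ribozyme filler + Shine-Dalgarno + ORF + filler +
3' motif, inserted at random positions and strands into 12 kb records with
bacterial taxonomy. Decoy RT families are seeded from intron IEPs at 55%
identity - close enough that the permissive initial search still finds
them, far enough (>= 35% divergence from every intron IEP) that the
top-three vote cleanly rejects them. Divergence is substitution-only at
exact counts, so identity targets and Hamming oracles are exact; indels
appear only in designated decoys. Identity-cluster members are mutated on
disjoint position sets around a common center, which makes every pairwise
identity hit the target exactly.

Default study conditions: 8 classes x 5 full introns plus one 3-member 95%
cluster spanning two species (43 full introns), and 25 decoys (6 truncated,
6 frameshifted, 5 premature-stop, 5 non-group-II RT, 3 twintrons). Planted
boundary termini match the class consensus exactly at fixed positions
(degenerate IUPAC positions vary); the noisy condition used to probe
robustness mutates motifs at 10% per column. The fixtures emulate sequence divergence,
truncation, frameshifts, nested copies and strand orientation; they do not
emulate ribozyme secondary structure, compositional bias, sequencing error
or real taxonomy, so green tests certify the pipeline's logic and
statistics, not its recall on real GenBank data.

## Numerical and degenerate-input choices

Ambiguity codes are preserved in sequences but act as universal mismatches
in scoring (protein X; profile columns emit their minimum log-odds), so
ambiguity never fabricates signal. Alignment tie-breaks are deterministic
(earliest best cell; match state preferred), and all rankings break E-value
ties by raw score then lexicographic id. The ML-distance optimizer returns
0 for identical sequences and errors when no comparable columns remain.
Empty corpora produce empty outputs with a warning and exit status 0; a
missing prior storage folder is an error naming the gap. Problem sizes in
the test suite (a 2-class corpus for unit tests, the default suite for the
end-to-end checks, 1000-window calibration, 50-pair distance simulations)
were chosen to keep the whole suite comfortably inside a desk-scale run
while leaving every statistical margin wide.

## Known limitations

The engine performs exact DP without heuristic seeding, so corpus scale is
bounded by CPU rather than by statistics. CL1 5' insertions and class B 3'
extensions - variant termini that defeat profile-anchored boundary calling
generally - are out of scope, as are ORF-less and LAGLIDADG-encoding introns and any RNA
secondary-structure validation. Live GenBank retrieval is represented only
by the local-file interface; the remote adapter is intentionally absent
from the offline build.
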