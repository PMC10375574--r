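---
title: "Methods: top-down MS/MS assessment of guide RNA spacer fidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: top-down MS/MS assessment of guide RNA spacer fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerms)
```

## The problem

Single guide RNAs (sgRNAs) for CRISPR nucleases are ~100-mer synthetic RNAs.
The first 20 nucleotides from the 5' end — the *spacer* — select the genomic
target, so a single-base substitution there can redirect editing to an
off-target site. Synthesis of long, heavily modified oligonucleotides
(2'-O-methyl riboses, phosphorothioate linkages) is error-prone, and
sequence impurities at the percent level matter.

Top-down MS/MS interrogates the intact guide directly: collisional
activation cleaves the backbone P–O5' bond, producing *c*-ions (5'
fragments retaining the cleavage-site phosphate or thiophosphate) and
complementary *y*-ions (3' fragments with a free 5'-OH). The c-ion ladder
c1..c20 reads out the spacer nucleotide by nucleotide, with every chemical
modification preserved. `spacerms` implements the computational side of
this assay end to end: mass and fragment arithmetic, isotopic envelope
prediction, spectrum preprocessing, cosine-gated fragment assignment with
decoy FDR, substitution discovery and quantitation (including C/U isotopic
mixture fitting), de novo spacer sequencing, and a seeded simulator so that
every stage is testable without instrument data.

## Mass and composition model

Sequences use a compact token syntax: `A`, `C`, `G`, `U`, optionally
followed by `(m)` (2'-O-methyl, +CH2 on the nucleoside) or `(ms)`
(2'-O-methyl plus a phosphorothioate on that nucleotide's 3' linkage; the
thio flag on a 3'-terminal nucleotide is rejected, since there is no 3'
linkage). Termini are fixed at 5'-OH/3'-OH, the synthesis convention for
these guides; this choice is validated by reproducing all six bundled
full-length average masses to better than 0.02 Da.

The composition of an oligo is the sum of its nucleoside compositions plus
one linkage acid per bond — phosphoric acid H3PO4, or thiophosphoric acid
H3PO3S where the 5'-side nucleotide is flagged — minus two waters per bond.
A c_n fragment adds the cleavage-site linkage acid of nucleotide n (minus
two more waters); a y_n fragment is simply the 3'-terminal n-mer. These
definitions make composition(c_n) + composition(y_(N-n)) equal the parent
composition exactly, which the tests enforce as an invariant, and they
reproduce the diagnostic c2 anchor m/z 670.0444 to within 0.001 (the
residual ~0.0005 reflects a proton/electron bookkeeping convention in
vendor software that we did not attempt to reverse-engineer).

Two atomic constant sets are stored. Monoisotopic masses are CODATA exact
masses of the lightest isotopes. Average masses use the older conventional
standard atomic weights (C 12.011, H 1.00794, N 14.00674, O 15.9994,
P 30.973762, S 32.066): the current IUPAC abridged weights place a ~33 kDa
guide about 0.12 Da below its conventionally printed average mass, while
the older set agrees to 0.015 Da across all six bundled guides, so it is
the set practitioners' numbers are actually computed with.

## Isotopic envelopes

Envelopes are aggregated by nucleon count: per-element natural isotope
vectors are convolved (exponentiation-by-squaring over atom counts), and
fine structure within a nucleon bin is collapsed to an abundance-weighted
centroid. This is adequate at QTOF resolution, where the matching
tolerance is 0.01 m/z and bins are ~1.00336/z apart. Peaks below 1e-4 of
the envelope maximum are pruned; unpruned bin probabilities sum to 1 within
1e-6, and the per-element convolution is tested against a brute-force
enumeration of all isotope assignments on small compositions.

Two constants fall out of the composition arithmetic and drive the C/U
machinery: a U-for-C substitution changes the neutral mass by 0.984 Da
(O vs NH), and the first 13C isotopologue of the C form sits only 0.019 Da
above the monoisotopic peak of the U form — unresolvable at z >= 2 with a
0.01 tolerance, which is why C/U calls need mixture fitting rather than
peak picking.

## Spectrum preprocessing

`preprocess()` mirrors the acquisition pipeline for averaged QTOF MS/MS of
guide RNA: scans are averaged (point-wise for profile data on a shared
axis; centroided scans are pooled within 0.005 m/z, comfortably below the
0.01 matching tolerance), profile data are centroided by local-maximum
detection with an intensity-weighted centroid, then peaks below 500 counts
are removed as noise and peaks above 1310 m/z are removed to exclude the
dense, uninformative surviving-precursor region. The vendor's exact
centroiding algorithm is not public; the local-maximum scheme here is
deliberately simple and is documented as replaceable. Preprocessing is
idempotent on already-centroided, filtered input.

## Fragment assignment

A fragment ion is assigned when (i) each theoretical isotopologue finds its
nearest peak within 0.01 m/z (ties toward the higher-intensity peak), (ii)
at least 2 *adjacent* isotopologues are matched (not necessarily including
the monoisotopic peak), and (iii) the cosine between the theoretical
envelope and the aligned observed intensities exceeds 0.80. Unmatched
theoretical positions contribute zero observed intensity, so the score is
scale-invariant and penalizes missing structure. The reported abundance is
the observed intensity at the most abundant theoretical isotopologue; the
mass error is recorded at the most intense matched isotopologue. A peak may
serve two overlapping fragments — overlap lowers the cosine rather than
forbidding reuse.

The decoy FDR shifts all theoretical m/z values by each nonzero offset in
-1000..+1000 ppm in 50 ppm steps (40 decoy searches); FDR is the mean decoy
hit count over the zero-offset hit count. One behavior worth knowing: even
on noiseless synthetic spectra the decoy rate does not reach exactly zero
(~3% at the 0.80 threshold), because a ppm shift near an integer multiple
of the isotopologue spacing re-aligns the broad envelope of a large c-ion
with a real envelope — the same congestion-driven floor seen on real
spectra. The tests therefore assert FDR < 5% on clean spectra plus a strict
decrease when the cosine threshold is applied, rather than exact zero.

## Substitution discovery and quantitation

Discovery enumerates all single-base permutations of the spacer (n x 3
candidates; C<->U excluded by default, see below). A substitution at
position n is only visible through c_n..c_m (m = spacer end), so each
candidate is scored as

  score = (coverage of c_n..c_m)^2 x sum over accepted unique fragment
  ions of abundance x cosine^2.

Isomeric candidates (e.g. G>A at positions 3, 4, 11 sharing c11..c20
masses) legitimately co-score; the per-type maximum view
(`substitution_type_summary()`) is the headline output. On simulated 10%
spike-ins of a position-11 G>A variant the true candidate ranks first and
the G>A type dominates all others.

Site quantitation for a *known* variant reports
100 x A_variant / (A_variant + A_parent) at each position. The charge
inventory is anchored on charges where either species passes the
acceptance gates, and both species are then read at their most abundant
theoretical isotopologue at those charges. The literal alternative — sum
only each species' own accepted matches — biases ratios low whenever
congestion from a co-occurring envelope distorts a minor isotopologue of
the low-abundance species and knocks out that charge's cosine; anchoring
the inventory keeps per-charge ratios unbiased, and on noiseless
simulations recovery is within 1 percentage point at every unique position.
Positions where parent and variant fragments share a composition (all
substituted sites beyond n) are flagged indistinguishable.

## C>U / U>C mixture fitting

For C/U interconversions the two envelopes interfere instead of
separating, so the observed envelope is modelled as
(1-f) x parent + f x substitute on a shared m/z grid (bin 0.2/z, below
half the isotopologue spacing). Stage 1 is non-negative least squares on
the two-column design; with two columns the NNLS solution is computed
exactly by enumerating the four active sets, which is deterministic where
iterative solvers can stall on near-degenerate designs. Stage 2 refines f
by minimizing the cosine distance between the mixture envelope and the
observation. On noiseless mixtures the fraction is recovered within 0.02
over f in {0, 0.01, 0.05, 0.1, 0.5}.

`cu_profile()` applies the fit to every c_n across the spacer (the
substitute composition does not depend on which U or C within the fragment
is substituted, so one fit per fragment suffices). Two robustness rules
matter in practice. First, because the parent ladder is known, a charge
state whose substitute-diagnostic bins coincide within tolerance with
another theoretical fragment ion of the ladder is excluded as interfered —
without this, ladder congestion injects 10-20% spurious substitution calls
at isolated positions even on clean spectra. Second, surviving per-charge
fractions are combined by their median rather than their mean, discounting
residual single-charge interference. A substitution at site s then appears
as near-zero percentages for n < s and a plateau near the molar fraction
for n >= s; `cu_site_summary()` averages the plateau.

## De novo sequencing

`denovo_spacer()` reconstructs the spacer 5' to 3' on a scaffold of
"empty" nucleotides that fixes only the modification flags. At each
position every surviving partial sequence is extended by A/G/C/U and kept
only if a matching c_k ion is found at some allowed charge. C and U
extensions are resolved jointly: whichever matches, the observed envelope
is mixture-fitted, and both branches are carried when the minority
fraction is at least 5% (below that, the majority call only). At
checkpoints k = 5, 10, 15, 20 candidates are scored by the
coverage-squared rule and every set of equal-mass partial sequences is
reduced to its best scorer (ties broken lexicographically), which
suppresses sequence scrambles. The default search demands full coverage;
the tag variant (`denovo_impurity_tags()`) tolerates one missed fragment
per five nucleotides — branching over all four bases at a miss — but
always requires c1, c2 and c3, which are the most abundant ions in these
spectra. On noiseless simulations the true spacer ranks first for all six
bundled guides, and the checkpoint search agrees with exhaustive
enumeration on small instances (length 6 over {A, G}).

`denovo_modifications()` inverts the problem: bases known, flags unknown,
searched over {unmodified, 2'-O-methyl, 2'-O-methyl + phosphorothioate}
(the chemistry vocabulary of these guides: a thio linkage implies a
methylated ribose). Full c-ion coverage is required over positions 1..20
and up to 2 missed cleavages are allowed over 21..28, beyond which c-ion
coverage is too sparse to localize. When a flanking fragment is missing,
compensating flag placements tie on score; `localize_modifications()`
reports the run of disagreeing positions as a localization stretch (e.g.
"methyl within 21..22") instead of guessing a single site.

## The simulator and what it does (not) show

`simulate_msms()` emulates an averaged negative-mode QTOF MS/MS spectrum
of a guide mixture. Its defaults are the conditions the package is
validated under:

* c-ion ladder c1..c20, charges 1-..7-, within a 100..1310 m/z window;
* per-fragment response decaying as exp(-k n) with k = log(20)/18, so c20
  carries ~5% of c2's signal — reproducing the observed sensitivity
  ordering (a 1% component is detectable at c2..c10, a 5% component at
  c15..c20, over a 500-count noise floor with amplitude 1e6);
* the fragment's signal split geometrically over its in-window charges
  (1/2, 1/4, ...), lowest charge dominant — a flat split would push second
  isotopologues of 1% components below the noise floor and contradict the
  stated sensitivity;
* independent Gaussian m/z jitter (sd 0.003) per peak, exponential noise
  peaks (mean 500), optional dense precursor-region signal above 1310 to
  exercise the cutoff, and merging of peaks closer than 0.01 m/z to mimic
  finite resolving power;
* full determinism under a fixed seed.

The simulator reproduces envelope congestion between ladder ions, which is
the dominant artifact on real spectra, but not chromatographic drift,
adduction, in-source fragmentation, detector saturation, or
sequence-dependent fragmentation efficiency (every fragment of a given
index responds identically, which is why simulated quantitation is more
linear than instrument data). Passing tests therefore demonstrate the
correctness of the algorithms under controlled conditions, not instrument
performance.

## Numerical choices and problem sizes

Defaults: tolerance 0.01 m/z; cosine threshold 0.80; at least 2
consecutive isotopes; noise floor 500 counts; m/z cutoff 1310; spacer
charges 1-..7-; full-length charges 1-..25-; envelope pruning 1e-4;
mixture grid 0.2/z; centroid pooling 0.005 m/z; C/U branch threshold 5%;
modification missed-cleavage budget 2. Isotope distributions are memoised
by formula. The test suite and acceptance script run simulations at the
scale of single averaged spectra of 100-mer guides (tens of fragment ions,
a few thousand peaks) with spike-in series at 1/5/10/50%, the sizes the
assay itself uses.

## Known limitations

Only 2'-O-methyl and phosphorothioate modifications are modelled (the
parser rejects everything else; extending the nucleoside/linkage tables is
the intended extension point). a/b/d/w/x/z ions and internal fragments are
not generated. De novo from the 3' end (y-ion ladders) is not implemented.
Multi-site simultaneous substitutions are only reachable through the de
novo path, not through the single-substitution discovery scorer. mzML
support is read-only and requires `mzR`; the native interchange format is
the headerless two-column TSV peak list.
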