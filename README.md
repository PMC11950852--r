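# DisplaySelect

Affinity selection from mRNA-display libraries (RaPID-style thioether
macrocycle campaigns) discovers peptide binders by iterating translation,
target capture, washing and PCR re-amplification over libraries that can hold
anywhere from 10^6 to 10^14 unique sequences. How much the *diversity scale*
of the starting library matters — which binder families a small library can
even contain, which families win the round-by-round competition, and how much
slower the best binder's dissociation rate gets per decade of diversity — is
the question this package is built around.

`DisplaySelect` provides, as one pipeline:

* **Library-scale arithmetic** — NNK sequence space (`32^L` DNA diversity),
  ribosome/mRNA budgets under the monosome assumption (one fusion per
  ribosome), subset lineages with dilution, and construct translation with
  architecture checks (initiator ClAc-Tyr token, NNK random region, fixed
  Cys, linker).
* **A 1:1 Langmuir kinetics core** — association dynamics
  `f(t) = kaC/(kaC+kd) · (1 − e^−(kaC+kd)t)`, wash survival `e^(−kd·n·t)`,
  log-scale (geometric) family averaging with the identity
  `K_Davg = k_davg / k_aavg`, sensorgram simulation and global 1:1 fitting.
* **A stochastic campaign simulator** — translation sampling under a ribosome
  budget, negative selection by stickiness, kinetics-governed positive
  selection with per-copy survival
  `p = ε_capture · f_bound · w_retention + stickiness · carryover`,
  and PCR re-amplification with point mutation (transition:transversion 3:1).
  Molecule counts are aggregated doubles, so 10^14-molecule campaigns run in
  seconds on a laptop.
* **NGS enrichment analysis** — FASTA/FASTQ read counting, the 2%-of-reads
  positive-clone triage, cross-library deduplication, ungapped Hamming
  single-linkage family clustering with per-position consensus sets,
  population trajectories, and best-binder kinetic scatter tables.
* **An extreme-value model** — with log10 k_d normally distributed across a
  random library, the expected best (minimum) k_d of N members is
  `mu + sigma · Φ⁻¹(0.625/(N+0.25))`; the spread `sigma` can be calibrated
  directly from a diversity-scaling statement such as "a 10^7-fold larger
  library gives a 10-fold slower best k_d".

## Worked example

```r
library(DisplaySelect)

# kinetics arithmetic
dissociationConstant(KineticParams(ka = 2.44e5, kd = 51.8e-3)) * 1e9
#> 212.3  (nM)

familyLogAverage(list(KineticParams(5.2e5, 3.9e-3), KineticParams(6.7e5, 4.5e-3)))
#> FamilyKinetics (n = 2): ka_avg = 5.9e+05 /M/s, kd_avg = 0.00419 /s, KD_avg = 7.1e-09 M

# extreme-value scaling: calibrate sigma so 7 decades of diversity buy a
# 10-fold slower best kd, then read the relation back
sigma <- calibrateSigma(10, 7)        #> 0.39
foldImprovement(1e6, 1e13, sigma)     #> 10

# a full synthetic campaign: the largest library of the default fixture
bundle <- generateCampaignFixture(defaultFixtureSpec(), seed = 1)
lib <- bundle$libraries$E14
res <- runCampaign(lib$state, bundle$config, nRounds = 7,
                   library = "E14", seed = 1, budgets = lib$budgets)
roundSummary(res)
#>   round   input recovered recoveryRate
#> 1     1 1.1e+14  1.10e+09     1.00e-05
#> 2     2 1.8e+12  1.80e+07     1.00e-05
#> 3     3 1.8e+12  1.84e+07     1.02e-05
#> 4     4 1.8e+12  6.20e+07     3.45e-05
#> 5     5 1.8e+12  1.86e+09     1.03e-03
#> 6     6 1.8e+12  2.80e+09     1.56e-03
#> 7     7 1.8e+12  2.82e+09     1.57e-03

triagePositiveClones(readTables(res)[[7]], TriageConfig())
#>          sequence count fraction rank
#> 1 VNFCGVRIGRWCECM 24742   0.2474    1
#> 2 YNFCGVRDGIWCECM 23127   0.2313    2
#> 3 YNFCGVRWGRWCECP 10993   0.1099    3
#> 4 YNFCGVRDLRWCECM 10227   0.1023    4
#> 5 YNFCGVRDSRECECM  7405   0.0741    5
#> 6 SNFCGVRDGRWCECM  2975   0.0297    6
```

Reading the output: recovery sits at the background level (~0.001% of input
molecules) while no binder is enriched, lifts off once the strongest planted
family passes ~1% of the pool (round 4 here), and plateaus near that family's
own survival probability. The triaged clones of the final round are all
variants of the slow-dissociating F-I family — in the smallest library of the
same fixture the winner is instead the fast-dissociating but universally
sampled F-IV family, the diversity-scale effect the simulator is built to
expose.

A command-line wrapper with `fixtures` / `simulate` / `analyze` / `evt`
subcommands is installed at `inst/scripts/displayselect`.

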