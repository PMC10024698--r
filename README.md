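# pvsignal

Disproportionality analysis for spontaneous adverse-event reporting
databases (FAERS-style extracts): signal detection for drug–event pairs
from 2×2 contingency tables, with stratified subgroups, a
published-row reconstruction tool, and a seeded synthetic report
generator with known ground truth.

## Who this is for

Pharmacovigilance analysts and methodologists who have a cleaned, flat
report extract (one row per report version: demographics, drug list,
reaction preferred terms, outcomes) and want a tested, reproducible
pipeline for the classical screening statistics — rather than a
spreadsheet. The worked focus is the association between periostitis and
the triazole antifungals (fluconazole, itraconazole, voriconazole,
posaconazole, ravuconazole), but every drug/event/threshold is
configurable.

## The statistics

For a drug D and event E, each deduplicated case falls in one cell of

|                 | E  | other events |
|-----------------|----|--------------|
| D               | a  | c            |
| all other drugs | b  | d            |

and the package computes, with Woolf-type 95% intervals:

- χ² = (ad − bc)²·N / ((a+b)(c+d)(a+c)(b+d)), optionally
  Yates-corrected;
- RRR (rate-ratio form (a/(a+b))/(c/(c+d)), or observed/expected
  aN/((a+b)(a+c)));
- PRR = (a/(a+c))/(b/(b+d));
- ROR = (a/c)/(b/d);
- IC = log₂(RRR).

A positive signal follows the Evans rule: n > 3, χ² > 4 and PRR > 2.

## Worked example: auditing a published summary row

Published tables print n, RRR, PRR and ROR but not the underlying cells.
`reconstruct_table()` recovers every integer table consistent with the
printed row, and the statistics can then be recomputed and checked:

```r
library(pvsignal)

sols <- reconstruct_table(143, 583.6, 1808.9, 1831.7,
                          rrr_method = "observed_expected")
nrow(sols)            # 21333 candidate tables, all with b = 68
t <- representative_solution(sols, 583.6, 1808.9, 1831.7)
print(t)
#> 2x2 contingency table: reconstructed / reconstructed [overall], N = 9,851,584
#>                  event other events
#> drug of interest   143        11297
#> all other drugs     68      9840076

compute_all(t, rrr_method = "observed_expected")
#>   N    143
#>   chi2 83,271
#>   RRR  583.6 (530.8, 641.7)
#>   PRR  1808.9 (1356, 2412.9)
#>   ROR  1831.7 (1371.6, 2446.3)
#>   IC   9.2 (9.1, 9.3)
round_half_up(chi_squared(t, correct = TRUE), 1)
#> [1] 82688.8
```

Reading: 143 cases reported both the drug and the event; the event is
reported ~1800 times more proportionally for this drug than for all
others (PRR, ROR agree at this sparsity), the pair clears the Evans rule
(`evaluate_signal(compute_all(t))` is `TRUE`), and the Woolf intervals
reproduce the published PRR/ROR intervals. The uncorrected χ² is 83,271;
the continuity-corrected value 82,688.8 is what matches the published
statistic. Note the row is only consistent under the observed/expected
RRR convention — with the rate-ratio formula the same call returns zero
solutions. See the methods vignette
(`vignettes/disproportionality-methods.Rmd`) for why.

## Full pipeline on synthetic data

```r
cfg <- synthetic_config(n_reports = 300000, seed = 42,
                        event_probs = c(Periostitis = 5e-3, Nausea = 0.06,
                                        Headache = 0.05, Rash = 0.04),
                        signals = data.frame(drug = "voriconazole",
                                             event = "Periostitis",
                                             theta = 20))
sim <- generate_reports(cfg)            # reports + ground-truth manifest
res <- run_analysis(sim$reports, analysis_config())
res$results[res$results$stratum == "overall", c("drug", "n", "ror", "signal")]
write_results(res, "out/")              # results.csv, characteristics_*.csv
```

The injected pair is flagged; the null triazoles are not. A command-line
wrapper ships in `inst/scripts/pvsignal.R`:

```sh
Rscript inst/scripts/pvsignal.R stats --a 20 --b 5 --c 5 --d 20
Rscript inst/scripts/pvsignal.R simulate --out reports.csv --seed 7 --n 50000
Rscript inst/scripts/pvsignal.R analyze --reports reports.csv --out out/
Rscript inst/scripts/pvsignal.R reconstruct --a 143 --rrr 583.6 \
    --prr 1808.9 --ror 1831.7 --rrr-method observed_expected
```

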