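# vrikshadx

A rule-based expert-system shell for diagnosing plant disorders in the
Vrikshayurvedic tradition, aimed at farmers, agronomy students, and anyone
studying how classical plant-life knowledge can be made queryable. The
tradition classifies plant disease two ways: **internal** disorders caused
by imbalance of the three doshas — *vata*, *pitta*, *kapha* — and
**external** disorders caused by insects, cold, wind, or sun. `vrikshadx`
ships that classification as a declarative knowledge base of ten disorders
with yes/no symptom questions and treatments (including the classical
Kunapajala fermented-manure recipe), plus a backward-chaining engine that
interviews an observer and explains its reasoning.

## The model

Each disorder $d$ has an ordered symptom list $S_d$ and one conjunctive
production rule

$$\big(\forall s \in S_d:\ \text{answer}(s)=\text{yes}\big) \implies d .$$

The engine works goal-directed: it takes each disorder in taxonomy order
(internal vata → pitta → kapha, then the external causes), asks only the
symptoms that rule needs, memoizes every answer so shared symptoms are
asked once, and rejects a hypothesis at its first "no". Alongside the hard
conclusion it tracks a graded belief, the confirmed-symptom fraction
$f_d = |\{s \in S_d : \text{yes}\}| / |S_d|$, used to rank near-misses when
nothing is confirmed — never to license a partial-match diagnosis. A
dialogue-free oracle (`brute_force_diagnose()`) and an evaluation harness
with a symmetric observation-noise model round out the shell.

## Worked example

```r
library(vrikshadx)

kb <- example_kb()
kb
#> <vriksha_kb> schema 1.0: 10 disorders, 33 symptoms, 5 treatments
#>   internal:
#>     vata: vata
#>     pitta: pitta
#>     kapha: kapha
#>   external:
#>     insects: insect_infestation
#>     cold: cold_injury
#>     wind: wind_damage
#>     sun: sun_scorch
#>     general: etiolation, bud_arrest, sap_exudation

# a plant presenting exactly the vata indications
answers <- setNames(
  ifelse(kb$symptoms$id %in% disorder_body(kb, "vata"), "yes", "no"),
  kb$symptoms$id
)
d <- diagnose(kb, answers)
d
#> <vriksha_diagnosis>
#>   confirmed: vata (primary: vata)
#>   questions asked: 13; hypotheses evaluated: 10
```

Thirteen questions sufficed for all ten hypotheses: the four vata symptoms
confirm the first goal, and each remaining hypothesis is rejected by a
single "no" on its first symptom (memoization re-asks nothing). The belief
statement names the conclusion, its place in the taxonomy, and the
treatment:

```r
cat(render_belief_statement(d, kb))
#> Belief statement: the plant has been classified as having:
#> - Vata disorder ('vata', internal > vata) [primary]
#> Recommended treatment for Vata disorder:
#> - Application of Kunapajala, the traditional fermented liquid manure, to
#>   restore the plant's dosha balance and vigour. (ingredients: hog fat,
#>   porpoise oil, ghee, hemp, horse hair, boiled cow horn, punchmula)
#> - Paste of medicinal herbs applied to affected bark and branches.

cat(explain_how(d))
#> Reasoning trace (13 question(s) asked):
#> - Hypothesis 'vata': CONFIRMED — every symptom present (dry_leaves=yes,
#>   rough_texture=yes, wilting=yes, stunted_growth=yes).
#> - Hypothesis 'pitta': REJECTED — decided by inflamed_tissue=no (...)
#> ...
```

The evaluation harness recovers every disorder from its own noise-free
presentation:

```r
m <- evaluate_cases(kb, generate_cases(kb, noise_rate = 0, master_seed = 1))
glance(m)
#> # A tibble: 1 × 3
#>   accuracy mean_questions n_cases
#>      <dbl>          <dbl>   <int>
#> 1        1           12.4      10
```

`tidy()`/`glance()` give broom-style views of diagnoses and metrics, and
`autoplot()` draws the belief state and the confusion matrix. A scripted or
interactive terminal interface lives behind `vriksha_cli()` (wrapper in
`inst/cli/vrikshadx.R`) with subcommands `diagnose`, `validate`,
`evaluate`, and `replay`:

```sh
Rscript inst/cli/vrikshadx.R validate --kb inst/extdata/vrikshayurveda_kb.json
Rscript inst/cli/vrikshadx.R evaluate --kb inst/extdata/vrikshayurveda_kb.json \
  --noise 0.3 --n 10 --seed 7 --out metrics.json
```

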