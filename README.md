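# crtphenomap

Topological phenogrouping and risk stratification for cardiac
resynchronization therapy (CRT) upgrade cohorts.

Choosing between a CRT-pacemaker (CRT-P) and a CRT-defibrillator
(CRT-D) at upgrade is difficult: the survival benefit of the
defibrillator is concentrated in a subset of patients. This package
implements a phenomapping pipeline for that problem, aimed at
biostatisticians and cardiology researchers:

1. **Network** — a Mapper-style topological patient-similarity network
   from 16 pre-upgrade clinical features: mean imputation, Z-scoring,
   normalized-correlation distance *d*(i,j) = 1 − r(i,j), two classical
   MDS lenses, an equalized cover (resolution 25, gain 2.1, i.e.
   ~52% interval overlap), single-linkage clustering within cover
   cells with a histogram-gap cut, edges between nodes sharing a
   patient, and removal of components disconnected from the main
   network.
2. **Phenogroups** — Louvain autogrouping of the node graph (edge
   weight = shared patients, resolution tuned towards 14 communities),
   then greedy merging of adjacent groups with the most similar crude
   mortality — under a group-size balance cap — down to exactly three
   phenogroups labeled low/intermediate/high risk; unique patient
   labels by majority node membership with ties towards higher risk.
3. **Survival** — study censoring rules (10-year horizon, subsequent
   CRT-D upgrade, transplantation, query date), Kaplan–Meier with
   Greenwood variance and log–log CIs, reverse-KM follow-up, k-group
   log-rank, Cox proportional hazards (Efron ties), and a clinical
   subgroup forest of the device effect.
4. **Classifier** — 5×5 nested cross-validation (inner grid search by
   balanced accuracy over multinomial logistic, random forest,
   gradient boosting, RBF SVM and MLP; outer evaluation), yielding an
   ensemble of 5 tuned models that assigns new patients to the
   phenogroups by averaged class probabilities.

Patient-level CRT-upgrade data are private, so the package includes a
synthetic cohort generator (`sim_config()` / `generate_cohort()`) with
three planted phenogroups carrying published-profile-like features,
exponential survival with group hazards in ratio 1 : 1.618 : 2.632, a
CRT-D hazard ratio of 0.454 planted in the high-risk group only,
10-year administrative censoring and MCAR feature missingness. All
tests and the analysis scripts run end to end on it.

## Worked example

```r
library(crtphenomap)

sc  <- generate_cohort(sim_config(n_patients = 1000, seed = 20260101))
run <- run_phenomap(sc$cohort)          # network + phenogroups
print(run$partition)
#> Phenogroup partition (14 autogroups -> 3):
#>     phenogroup n_patients n_events mortality
#> 1          low        108       59 0.5462963
#> 2 intermediate        452      298 0.6592920
#> 3         high        280      222 0.7928571
#> 13 patient(s) with multi-group membership
```

The three phenogroups are ordered by observed mortality (here 55%,
66%, 79% crude death rates among 827 retained patients; 173 patients
in minor network components were set aside as outliers). Survival
contrasts and the device effect per phenogroup come from
`phenomap_survival(run, sc$cohort)`; training the classifier ensemble
on the phenogroup labels:

```r
x   <- encode_features(sc$cohort)[!is.na(run$assignment$phenogroup), ]
y   <- droplevels(run$assignment$phenogroup[!is.na(run$assignment$phenogroup)])
ens <- nested_cv_train(x, y, nested_cv_config(seed = 1))
print(ens)
#> Phenogroup classifier ensemble: 5 members
#>   selected families: mlp, mlp, mlp, mlp, multinomial
#>   balanced accuracy: 0.908 (0.889-0.926)

predict_ensemble(ens, new_cohort)   # phenogroups for new patients
```

A balanced accuracy of 0.908 means the ensemble recovers the
network-derived labels from the raw features with ~91% average
per-class recall; the micro-averaged AUC in the same run is 0.986.

The numbered drivers under `analysis/` run the full study workflow
(simulate → network → phenogroups → survival → classifier) and write
tables, plots, GraphML/JSON network exports and metric reports under
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_network.R
Rscript analysis/03_phenogroups.R
Rscript analysis/04_survival.R
Rscript analysis/05_classifier.R
```

## A note on recovering planted structure

The default generator mirrors realistic, *overlapping* clinical
profiles: the intermediate-risk profile interpolates between the low
and high ones, so the planted labels are only partly identifiable from
the features — even a Bayes-optimal classifier misassigns a
substantial fraction of patients. The pipeline therefore reproduces
the planted risk *ordering* and network gradient robustly, while
patient-level label agreement is intrinsically bounded and the device
effect within the recovered (rather than planted) high-risk group is
attenuated towards the null. See the methods vignette
(`vignettes/phenomapping.Rmd`) for the full discussion.
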