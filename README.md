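# caerus

Network-based gene signatures for cancer outcome classification, built on
the **domain-interaction structure** of the protein interactome.

Expression-only prognostic signatures transfer poorly between cohorts.
caerus instead anchors the signature in network structure: proteins whose
interactions are funneled through a single physical interface
("singlish-interface" hubs) are fragile points of the interactome — their
partners bind mutually exclusively, so one perturbation can disrupt many
interactions at once. The package scores every protein by that property,
selects high scorers as gene signatures, and classifies patients by how
strongly their expression profile decouples each signature from its
network neighbors.

## The model

For a protein $x$ with Pfam domains $D(x)$, each domain $d$ counts its
realized domain–domain interaction (DDI) instances with the domains of
$x$'s PPI neighbors, $\mathrm{NumDDIs}(d)$, and the protein scores

$$S(x) = \sum_{d \in D(x),\,\mathrm{NumDDIs}(d)\ge 1} 2^{\mathrm{NumDDIs}(d)},$$

optionally weighting each term by $1 + \mathrm{NumSMs}(d)$, the somatic
mutation count of the domain. Proteins with $S(x) > c$ become gene
signatures. Per patient, each signature's feature is the mean absolute
rank-scaled expression difference to its PPI neighbors (a value in
$[0,1]$); features are discretized into 20 bins and fed to a naive Bayes
classifier (good vs poor outcome). The threshold $c$ is tuned by nested
cross-validation: LOOCV inside each 80% training fold, validation on the
held-out 20%. See `vignettes/caerus-methods.Rmd` for the full account.

## Worked example

Everything runs on seeded synthetic data with known ground truth:

```r
library(caerus)

cfg <- sim_config(seed = 42)          # 5 planted hubs, degree 8, 200 proteins
sim <- simulate_bundle(cfg)
sim$bundle
#> <caerus_bundle> 200 proteins, 242 PPI edges, 200 annotated proteins, 14 DDI pairs, 5 mutated domains

domain_index_score(sim$truth$planted_signatures[1], sim$bundle)[c("score_plain", "score_mutation", "interface_class")]
#> hub P001 : plain = 256, mutated = 1024, class = singlish

select_signatures(score_all(sim$bundle), score_config(threshold_c = 50))
#> [1] "P001" "P002" "P003" "P004" "P005"    # exactly the planted hubs

coh <- simulate_cohort(sim, cfg)      # 60 good / 40 poor patients
cv  <- nested_cv(sim$bundle, coh, seed = 42)
cv
#> <caerus_cv> 5 folds | pooled acc=1.000 sens=1 spec=1 AUC=1.000 (seed 42)
```

The planted hub scores $2^8 = 256$ because its single domain realizes 8
DDI instances through one interface (hence `singlish`); with 3 recorded
mutations on that domain the weighted score is $256 \times 4 = 1024$.
Signature selection at $c = 50$ recovers exactly the 5 planted hubs, and
nested CV separates the two outcome classes perfectly at the default
planted effect size. With `effect_delta = 0` (null cohort) pooled
accuracy collapses to the majority-class rate and AUC to ~0.5.

## Command line

A thin CLI over the same functions lives at `inst/cli/caerus.R`
(subcommands `simulate`, `score`, `signatures`, `features`, `train`,
`predict`, `cv`):

```sh
Rscript inst/cli/caerus.R simulate --out simdat --seed 5
Rscript inst/cli/caerus.R cv --ppi simdat/ppi.tsv --annotation simdat/annotation.tsv \
    --ddi simdat/ddi.tsv --mutations simdat/mutations.tsv \
    --expression simdat/expression.tsv --labels simdat/labels.tsv \
    --out simout --seed 5
```

Input formats are plain TSV: PPI edge list, protein–domain annotation,
DDI catalog, domain mutation counts (two columns each, `#` comments), and
an expression matrix (genes × patients, header row of patient ids) with a
two-column outcome label file.

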