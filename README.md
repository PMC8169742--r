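# pathclock

Interpretable transcriptomic age clocks built as **knowledge-primed
artificial neural networks**.

Age clocks predict chronological age from molecular data and read the
deviation between predicted and actual age as a biological-age signal. Most
clocks are black boxes: accurate, but silent about the processes driving
their predictions. `pathclock` is for aging researchers who want both — a
clock whose internal structure *is* the biology. Gene-set annotation (any
GMT collection; canonically the 50 MSigDB Hallmark sets) is compiled into a
binary gene × pathway filter matrix that constrains the network's
connectivity: genes feed only the hidden neurons of pathways they belong
to, hidden layers are dense within a pathway and disconnected across
pathways, and each pathway culminates in a single linear neuron whose
activation is a per-pathway age estimate ("pathway age").

The model, in brief:

- per-pathway hidden width `w_p = 5 + floor(n_p / f)` with neuron scaling
  factor `f = 2` (base width 5, capacity grows with pathway size);
- four hidden pathway layers, elu activations, He initialization, unit
  dropout 0.1 between hidden layers, global L2 weight decay 0.01;
- combined loss `(1 − α)·MSE_main + α·MSE_aux` with `α = 0.4`, where the
  auxiliary target is the chronological age broadcast to every pathway
  neuron — this trains each pathway sub-network to be its own small clock;
- Adam (lr 0.001), mini-batches of 16, 200 epochs, 70/30 train/test split;
- a stacked ensemble of 10 independently trained members whose main and
  auxiliary outputs are averaged.

On top of a fitted clock the package provides in silico perturbation —
single-gene knockdown/overexpression at a log2 fold-change (default −2),
dose–response curves, genome-wide knockdown scans, and complex
differential-expression signature perturbations with an FDR < 0.05 filter —
plus pathway statistics: activation–age correlation ranking against an
artificial control pathway of randomly sampled genes (one-sided Wilcoxon
rank-sum tests vs the control, Holm-adjusted), age-stratified signed-rank
effect tests, the "crossroads" association between pathway multiplicity and
knockdown impact, and a tSNE embedding of the pathway perturbation
landscape. A linear-Gaussian synthetic-data generator with planted,
pathway-structured age effects makes the whole pipeline testable without
access-restricted cohort data.

## Worked example

```r
library(pathclock)

# synthetic benchmark: 500 samples, 4 pathways x 40 genes, one pathway
# planted with a linear age effect (slope 0.05 / year, sigma = 1)
sim <- simulate_aging_dataset(seed = 1)
fit <- pathclock(sim$expr, sim$ages, sim$membership, n_members = 3, seed = 1)
summary(fit)
#> Ensemble age clock: 3 members, 12,009 parameters per member
#>   training fold (n = 350): MAE 1.56 years, r = 0.997
#>   test fold     (n = 150): MAE 7.09 years, r = 0.917

# pathway ages: the planted pathway dominates the age correlation
round(activation_age_correlation(predict(fit, type = "pathways"),
                                 sim$ages[fit$data$test]), 3)
#>   PW01   PW02   PW03   PW04
#>  0.981  0.144 -0.028  0.035

# in silico knockdown of a planted positive-slope gene rejuvenates
knockdown_effect(fit, sim$truth$planted_genes[1])
#> In silico perturbation: g0001 log2FC -2
#>   1 gene(s) applied, 0 skipped; 150 samples
#>   median delta age: -0.557 years (IQR -0.697 to -0.348)
```

The test-fold MAE of ~7.1 years beats the mean-age predictor (~15 years on
uniform 30–89 ages); the planted pathway PW01 carries the top
activation–age correlation (r = 0.98) while unplanted pathways stay near
zero; and knocking down a gene whose expression rises with age shifts
predictions younger, as the planted effect dictates.

For real data, replace the generator with your own inputs:

```r
gmt <- read_gmt("hallmark.gmt")
expr <- read_expression("expression.tsv")   # samples x genes, TPM
ages <- read_ages("ages.tsv")
m <- build_membership(gmt, colnames(expr))
clock <- pathclock(expr, ages, m, scale = "linear", n_members = 10, seed = 1)
```

A command-line interface wrapping the same functions is installed at
`exec/pathclock` (subcommands `simulate`, `train`, `predict`, `knockdown`,
`scan`, `signature`, `rank`, `map`).

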