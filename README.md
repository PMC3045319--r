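# orgfocus

Classify biomedical articles by their **focus model organism**.

Organism databases (FlyBase, MGD, SGD, ...) are curated from the literature by
hand, and the first step of curation is routing: deciding which model organism
an article's experiments actually concern. That is harder than it sounds —
papers routinely *mention* several species (orthologs, host models, outgroups
in phylogenies) while being *about* one. `orgfocus` implements a complete,
self-contained pipeline for this routing problem for a configurable label set
(fly = *Drosophila melanogaster*, mouse = *Mus musculus*, yeast =
*Saccharomyces cerevisiae* by default), together with the evaluation and
ablation machinery needed to study which signals matter.

## What is in the pipeline

1. **Corpus handling** — a line-delimited JSON record format for articles
   (title, journal, MeSH headings, typed sections), rule-based sentence
   tokenization, and heading-table section typing.
2. **Triage rule** — if a title mentions exactly one distinct organism, the
   article is labelled immediately and bypasses the statistical classifier.
3. **Content selection** — full texts are restricted to abstract,
   introduction, results and conclusion; for articles without recognizable
   headings a gene-section distribution is compared (cosine similarity)
   against a reference distribution over six contiguous token blocks.
4. **Mention tagging** — deterministic lexicon taggers for organism names
   (case-insensitive, longest n-gram match) and gene symbols
   (case-sensitive), with an optional symbol-pattern rule.
5. **Eight feature families** — per-document top-*n* gene counts (GN),
   organism mention frequency (OF), per-class frequent MeSH headings (MH),
   title organism/gene indicators (DT), the **term-species score** (TS),
   journal name (JN), count of corpus top-*n* genes present (NT), and
   additional gene names from a local synonym table (AGN).
6. **Learners** — from-scratch multinomial Naive Bayes with add-α smoothing
   (categorical journal feature handled as its own conditional table),
   bagging and AdaBoost.M1 ensembles over it, a section-sequence aggregation
   classifier, and a registry for plugging in external learners.
7. **Evaluation** — one-vs-rest P/R/F, stratified k-fold and repeated
   (runs × k) cross-validation on shared folds, the corrected resampled
   t-test, and an ablation harness producing model × feature-set × class
   tables.
8. **Synthetic corpus generator** — seeded labelled pseudo-articles with
   per-class Zipf gene vocabularies, a shared ambiguous gene pool, planted
   gene–species pairs with controlled distances, planted MeSH headings,
   journal pools, a ~5% multi-species fraction and a ~5% title-rule branch,
   so every stage is testable without external data.

### The term-species (TS) score

When a sentence contains both a gene mention g and an organism mention s,
the organism's evidence is weighted by the token distance d(g, s) between
them; contributions are summed over all co-sentence pairs in the article:

    TS(article, organism) = sum over co-sentence pairs (g, s) of w(d(g, s)),
    w(d) = 1 / (1 + d)            (default; exponential decay available)

A gene named right next to "Drosophila" is strong evidence that the article's
experiments concern fly, even when mouse orthologs are mentioned elsewhere.
TS is the feature that resolves multi-species articles; the package's
ablation machinery demonstrates its effect directly (see below).

## Worked example

```r
library(orgfocus)

# a synthetic corpus with the default study conditions: 3 classes,
# 300 docs/class, ~5% multi-species, ~5% title-rule titles
corpus <- generate_corpus(generator_config(docs_per_class = 300, seed = 1))
pipe <- pipeline_config(gene_lexicon = corpus$gene_lexicon,
                        synonym_table = load_synonym_table())

cv <- k_fold_cv(corpus$documents, "nb", parse_feature_set("full"),
                k = 10, seed = 1, pipeline = pipe)
print(cv)
#> <10-fold CV> learner=nb features=GN+OF+MH+DT+TS+JN+NT+AGN macro-F=1.000
#>   fly      P=1.000 R=1.000 F=1.000
#>   mouse    P=1.000 R=1.000 F=1.000
#>   yeast    P=1.000 R=1.000 F=1.000
```

With the default generator the signal is strong and Naive Bayes recovers
every label. The interesting cases are the stress presets. On the
ambiguity-stressed corpus (gene vocabulary fully shared across classes,
uninformative MeSH/journal/title, every organism mentioned at equal rates)
the basic feature set is at chance while adding TS restores most of the
performance:

```r
amb <- generate_corpus(ambiguity_stressed_config(docs_per_class = 80, seed = 2))
pipe <- pipeline_config(gene_lexicon = amb$gene_lexicon)
rcv <- repeated_cv(amb$documents,
                   cv_spec("nb", parse_feature_set("F1+TS")),
                   cv_spec("nb", parse_feature_set("F1")),
                   runs = 10, k = 10, seed = 2, pipeline = pipe)
corrected_resampled_ttest(rcv)[c("mean_diff", "t", "p_value")]
#> $mean_diff
#> [1] 0.508225
#> $t
#> [1] 13.88293
#> $p_value
#> [1] 5.725496e-25
```

A macro-F gain of ~0.51 for the term-species feature, significant under the
corrected resampled t-test over 10 × 10 cross-validation.

A thin command-line front end over the same functions ships in
`inst/cli/orgfocus.R` (`simulate`, `evaluate`, `ablate`, `compare`
subcommands).

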