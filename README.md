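# dagsynth

Causal inference from observational data stands or falls with the causal
diagram it assumes. In practice most directed acyclic graphs (DAGs) in
epidemiology are drawn from intuition, with no record of why each arrow
was kept, reversed, or left out. **dagsynth** implements a systematic,
auditable alternative: it derives a DAG from a body of reviewed studies,
one documented decision at a time, so that every edge in the final graph
can be traced back to the study, criterion, and rationale that produced
it.

The workflow has four stages:

1. **Mapping.** Each study's conclusions — exposures, outcomes,
   controlled covariates, reported mediators and instruments — are
   recorded as a `study_record()` and mapped into a *saturated implied
   graph*: every pair of variables carries an edge, because *omitting*
   an edge is the stronger causal claim and must be earned, not assumed.
2. **Translation.** Both directions of every candidate edge are passed
   through four sequential causal criteria — temporality, face
   validity, recourse to theory, and a counterfactual thought
   experiment. The pairwise verdicts resolve each edge to *retained*,
   *reversed*, *bidirectional* (latent common cause), or *deleted*.
   Every verdict lands in an append-only decision log that can replay
   the whole translation.
3. **Integration.** Retained edges from all studies enter a
   provenance-bearing *directed edge index*; conflicting directions are
   flagged, never silently merged. Synthesis unions the index into an
   *integrated DAG* (I-DAG) — an order-invariant operation — and
   reports *pending pairs*: variable pairs that never co-occurred in a
   single study and must now be assessed in the context of the combined
   graph. Nodes with identical neighbourhoods (or a theoretical
   equivalence argument) can be recombined into a single construct.
4. **Analysis.** The finished DAG is interrogated with d-separation,
   backdoor path enumeration, minimal sufficient adjustment sets,
   covariate role classification (mediator, confounder, collider,
   risk factor, instrument), and a what-if report on the consequences
   of adjusting for a proposed covariate set.

## Worked example

The package ships a complete demonstration review on adolescent alcohol
use: a hypothetical study of historical parental alcohol use and
adolescent drinking, and the Seljamo et al. study of parental predictors
of adolescent drinking. All study records and criteria assessments are
shipped as data files in the same formats the command-line interface
consumes.

```r
library(dagsynth)
ex <- alcohol_example()

ig <- map_study(ex$studies$hypothetical)
ig
#> <mixed_graph> stage=implied: 4 nodes, 6 edges (5 directed, 1 unassigned, 0 bidirectional), 0 recorded deletions
#>   adol_sex -> adol_alc [candidate]
#>   adol_sex -- adol_substance [candidate]
#>   adol_sex -> parental_alc_hist [candidate]
#>   adol_substance -> adol_alc [candidate]
#>   adol_substance -> parental_alc_hist [candidate]
#>   parental_alc_hist -> adol_alc [candidate]
```

Saturation produced all 6 pairs over 4 nodes: 5 directed candidates
(controls point at exposure and outcome until shown otherwise) and 1
unassigned control–control pair. Translation under the shipped verdicts
retains five edges and deletes the sex–exposure pair — adolescent sex
cannot plausibly be *caused by* parental history, and as a cause of the
outcome only it is a risk factor, not a confounder:

```r
tr <- translate_graph(ig, ex$assessments$hypothetical)
tidy(tr$graph)
#> # A tibble: 6 × 6
#>   tail              head              orientation status   confidence studies
#>   <chr>             <chr>             <chr>       <chr>    <chr>      <chr>
#> 1 adol_sex          parental_alc_hist <NA>        deleted  <NA>       hypotheti…
#> 2 adol_sex          adol_alc          directed    retained normal     hypotheti…
#> 3 adol_sex          adol_substance    directed    retained normal     hypotheti…
#> 4 adol_substance    adol_alc          directed    retained normal     hypotheti…
#> 5 parental_alc_hist adol_alc          directed    retained normal     hypotheti…
#> 6 parental_alc_hist adol_substance    directed    retained normal     hypotheti…
```

Every criterion verdict is in the decision log:

```r
tr$log[1:5, c("seq", "subject", "action", "verdicts")]
#> # A tibble: 5 × 4
#>     seq subject                       action                       verdicts
#>   <int> <chr>                         <chr>                        <chr>
#> 1     1 parental_alc_hist -> adol_alc criterion:temporality        yes
#> 2     2 parental_alc_hist -> adol_alc criterion:face_validity      yes
#> 3     3 parental_alc_hist -> adol_alc criterion:recourse_to_theory yes
#> 4     4 parental_alc_hist -> adol_alc criterion:counterfactual     yes
#> 5     5 adol_alc -> parental_alc_hist criterion:temporality        no
```

`alcohol_pipeline()` runs both studies end to end: translate, index,
merge, synthesise. Synthesis surfaces six pending pairs — combinations
like adolescent sex and family structure that no single study examined
together:

```r
res <- alcohol_pipeline()
res$pending0
#> # A tibble: 6 × 2
#>   a              b
#>   <chr>          <chr>
#> 1 adol_sex       alc_initiation
#> 2 adol_sex       family_structure
#> 3 adol_sex       parental_alc_hist
#> 4 adol_substance alc_initiation
#> 5 adol_substance family_structure
#> 6 alc_initiation family_structure
```

After resolving the pending pairs with the shipped I-DAG-context
assessments (one new edge retained, five pairs deleted), the final
integrated DAG has 6 nodes and 10 edges, and the focal effect turns out
to need no adjustment at all — none of the suggested covariates
confounds it:

```r
glance(res$idag)[, c("stage", "n_nodes", "n_edges", "acyclic")]
#> # A tibble: 1 × 4
#>   stage      n_nodes n_edges acyclic
#>   <chr>        <int>   <int> <lgl>
#> 1 integrated       6      10 TRUE

minimal_adjustment_sets(res$idag, "parental_alc_hist", "adol_alc")
#> # A tibble: 1 × 2
#>   set        size
#>   <list>    <int>
#> 1 <chr [0]>     0
```

The analysis tools explain *why* naive adjustment would mislead here.
Adolescent substance use sits on the causal pathway and is a collider:

```r
classify_covariate(res$dags$hypothetical, "parental_alc_hist", "adol_alc",
                   "adol_substance")
#> # A tibble: 2 × 2
#>   node           role
#>   <chr>          <chr>
#> 1 adol_substance mediator
#> 2 adol_substance collider_on_path

adjustment_consequences(res$dags$hypothetical, "parental_alc_hist",
                        "adol_alc", "adol_substance")
#> <adjustment_consequences> parental_alc_hist -> adol_alc given {adol_substance}
#>   blocked causal paths (over-control):
#>     parental_alc_hist -> adol_substance -> adol_alc
#>   opened paths (collider bias):
#>     parental_alc_hist -> adol_substance <- adol_sex -> adol_alc  [collider: adol_substance]
```

Graphs interchange with the DAGitty model text format and Graphviz DOT:

```r
cat(export_dagitty(res$dags$hypothetical))
#> dag {
#> adol_alc [outcome]
#> adol_sex [control]
#> adol_substance [control]
#> parental_alc_hist [exposure]
#> adol_sex -> adol_alc
#> adol_sex -> adol_substance
#> adol_substance -> adol_alc
#> parental_alc_hist -> adol_alc
#> parental_alc_hist -> adol_substance
#> }
```

A thin command-line interface wraps the same functions
(`system.file("cli", "dagsynth", package = "dagsynth")`), with
subcommands `map`, `translate`, `index`, `synthesise`, `recombine`,
`analyse`, `export`, and `log`, reading and writing the package's YAML,
CSV, JSON, and NDJSON document formats.

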