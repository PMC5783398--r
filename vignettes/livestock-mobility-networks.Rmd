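---
title: "Analysing livestock mobility networks with herdflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing livestock mobility networks with herdflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdflow)
```

## The problem

In Sahelian livestock systems, animals move for two distinct reasons:
routine pastoral activity (transhumance between grazing areas, fostering of
herds with distant keepers) and trade, which surges sharply in the weeks
before Tabaski (Eid al-Adha), when millions of sheep are brought to urban
markets. Understanding where and when herds move is the basis for targeting
disease surveillance and vaccination, because the mobility network bounds how
far an epidemic introduced at one location can travel.

`herdflow` analyses such systems as directed, weighted origin--destination
(O-D) networks built from movement records: one row per recorded movement,
with origin, destination, month, species, head count, transport mode and the
declared activity at each endpoint. The package covers the full analysis
chain: ingestion and validation, network construction with monthly
snapshots, descriptive topology, dominant-flow decomposition, temporal
segmentation into mobility periods, persistence-based link classification,
and QAP correlation tests between networks. Because national movement
databases are rarely public, the package ships a synthetic generator that
emulates the statistical structure of such data with known ground truth, so
every stage can be validated end to end.

## Data model

A **gazetteer** holds one row per location: id, name, ISO-like country code,
WGS84 coordinates, and a semicolon-separated set of activities among
`zone_elevage` (any livestock-raising location: farm, pastoral zone or
village), `market`, `slaughterhouse` and `resting_area`. A `coord_source`
flag records whether coordinates came from GPS readings or from a commune
centroid; both are treated identically downstream.

A **movement table** holds one row per recorded movement. Months are
integers 1--12 — all analyses are monthly, so finer dates are reduced to the
month at ingestion. `read_movements()` validates every token, drops exact
duplicate rows, excludes (and counts) records whose endpoints are not in the
gazetteer, and derives the `scope` flag: a movement is *national* iff both
endpoints lie in the focal country, *international* otherwise.

```{r}
gaz <- generate_locations(sim_config(seed = 1))
gen <- generate_movements(gaz, sim_config(seed = 1))
head(gen$movements, 3)
```

`build_network()` aggregates all records of an O-D pair inside a month
window into one link carrying total volume (head count), movement count,
active months, and per-species/per-transport volume breakdowns. Following
the field convention, *frequency* always means a record count and *volume*
a head count. Self-loops (distinct names resolving to one id) are dropped
with a warning. A filtered network excludes isolated nodes, so per-species
node counts are smaller than the full gazetteer.

## The synthetic generator

`sim_config()` encodes the study conditions the generator emulates:

* **87 locations** (73 national, 14 international across the southern
  border), with national points concentrated in the south of the bounding
  box, where herds and people are.
* **147 aggregated O-D links** emitting roughly 2,300 records over a year.
* **A two-regime year**: routine months 1--8, then a Tabaski-driven regime
  from `regime_change_month = 9`. Per-record species mix (small ruminants /
  cattle / dromedaries) is 0.60/0.30/0.10 in the routine regime and
  0.81/0.12/0.07 in the Tabaski regime; truck transport probability rises
  from 0.07 to 0.50 and market-destination probability from 0.13 to 0.64.
* **Persistence classes** assigned per link first (backbone 0.31, frequent
  0.12, intermediate 0.45, occasional 0.12), then active months drawn
  consistently with the class.
* **Heavy-tailed destination choice**: destinations are drawn by
  preferential attachment (weight proportional to current in-link count plus
  one) with a boost for a handful of designated market hubs and an
  exponential distance decay with a 200 km scale, which by construction
  places most movements in the 100--300 km band.

Activity months form *runs* (seasonal campaigns), placed circularly within
the regime's month pool: intermediate links run mostly inside the routine
regime (probability 0.85) and occasional links inside the Tabaski regime
(probability 0.85); frequent links necessarily span both. Circular placement
treats the calendar year as an arbitrary window on an ongoing process and
gives every month of a regime the same coverage, avoiding artificial edge
effects at the regime borders.

Volumes are modelled as a persistent per-link base consignment size (drawn
from a species mixture of log-normal size distributions, so the cross-route
distribution stays heavy-tailed) times a modest monthly log-normal jitter
(`monthly_noise_sdlog = 0.35`). A route moves similarly sized herds all
year; treating herd sizes as independent per record would make monthly link
volumes far noisier than the weighted Jaccard profiles reported for real
systems. The seasonal `month_multiplier` acts on movement *frequency*
(April--June export peak, September surge, quiet year end), while
`regime_volume_scale = 0.4` shrinks per-record consignments in the Tabaski
regime: routine movements are composite transhumant herds, Tabaski
consignments are smaller market batches. The 0.4 follows arithmetically from
a monthly volume ratio of about 0.57 between the regimes combined with a
roughly 1.5-fold frequency rise at the regime change.

`generate_movements()` returns the table together with a `ground_truth`
object: the planted class of every link, the period partition, the hub set,
and the realized per-regime transport/species/destination shares. All draws
come from one seeded stream (`generate_locations()` seeds with `seed`,
`generate_movements()` with `seed + 1`), so identical configurations give
byte-identical outputs.

What the generator does **not** emulate: reporting biases of certificate
surveys, within-month timing, multi-year dynamics, herd demography, route
geometry (movements are great-circle abstractions), and any disease process.
Passing recovery tests therefore shows the methods work on data with the
reported statistical structure, not that they are robust to every artefact
of real surveys.

## Descriptive topology

`degree_distribution_summary()`, `component_summary()` and
`clustering_and_diameter()` wrap standard graph algorithms. Two choices are
worth noting:

* **Clustering and diameter are computed on the undirected projection**, the
  diameter within the largest weakly connected component (unweighted hops).
  A directed O-D network of this kind is typically not strongly connected,
  so a single finite diameter is only meaningful direction-agnostically;
  `component_summary()` reports weak and strong component sizes explicitly
  so both readings of "connected" are available.
* **Power-law fits** (`fit_power_law()`) default to the Clauset-style
  maximum-likelihood estimator with `xmin` fixed at the minimum observed
  value, so the whole distribution is fitted, as is usual when exponents are
  read off log-log degree plots; a log-log least-squares fit on the
  histogram is provided for comparability with such plots. Exponents are
  reported as positive magnitudes. The goodness flag compares the
  Kolmogorov--Smirnov distance of the fitted tail against its asymptotic
  critical value; this ignores the effect of parameter estimation and is
  documented as approximate.

Distances are great-circle (haversine, Earth radius 6371.0088 km, the IUGG
mean radius). `distance_profile()` bins movements into half-open 100 km bins
by destination activity; `summarize_flows()` produces activity-by-activity
tables of counts, volumes and percentage shares, with a half-up-rounded
integer variant for comparison against printed tables (half-up because
printed reports round 92.5 to 93, whereas R's default rounds half to even).

## Dominant flows and nodal regions

The decomposition extracts the market hierarchy of the network in two steps:

1. `prune_minor_links()` keeps link $(i, j)$ iff
   $w_{ij} / \sum_k w_{ik} > 0.20$ — strictly more than 20% of the origin's
   outgoing volume. The strict inequality means an exact five-way 20% split
   retains nothing.
2. `nodal_regions()` takes, for each node $i$, the destination $j$
   receiving $i$'s largest outgoing volume; the link is *dominant* iff the
   total in-volume of $j$ strictly exceeds that of $i$. Dominant links form
   a forest (in-volume strictly increases along each parent chain, so no
   cycles are possible); its roots — parents with no dominant outgoing link
   of their own — are the dominant nodes, and their trees are their
   influence areas.

Ties on the largest-outflow destination are broken towards the destination
with larger total in-volume, then lexicographically, making the
decomposition deterministic. Pruning is applied before the dominance test
(pass `prune = FALSE` to evaluate the alternative), and only the single
largest-outflow destination of each origin is ever a candidate.

```{r}
net <- build_network(gen$movements)
nodal_regions(net)
```

## Temporal dynamics

Monthly snapshots are compared with two similarity indices: the plain
Jaccard index $J = |A \cap B| / |A \cup B|$ on node or link sets, and the
weighted Jaccard index on link-volume maps,

$$J' = \frac{\sum_{e \in A \cup B} \min(w_A(e), w_B(e))}
            {\sum_{e \in A \cup B} \max(w_A(e), w_B(e))},$$

with absent links contributing weight zero. When both snapshots are empty
the indices are defined as 1 (two empty months are identical; 0/0 is
otherwise undefined). With equal weights $J'$ reduces exactly to $J$. A link
is *active* in a month as soon as one animal moved — there is no volume
floor.

`detect_periods()` segments the year by contiguity-constrained agglomerative
clustering: pairwise snapshot dissimilarity is one minus a weighted mean of
the three Jaccard indices (default weights (0, 0, 1): the volume index
carries the seasonal signal in systems whose link set is more stable than
their traded volumes); adjacent clusters are merged greedily under average
linkage. With a fixed `n_periods` the merge sequence is replayed to that
size. In automatic mode the number of periods is chosen by maximising the
mean silhouette width over the partitions the merge sequence generates
(singletons contribute zero; if all snapshots are identical one period is
returned). An earlier design cut at the largest jump in the merge-cost
sequence, but that rule is degenerate: the first merge cost is the minimum
of eleven noisy dissimilarities, so its gap to the second merge is inflated
even when no structure exists, and average-linkage costs drift upward with
cluster size regardless of structure. The silhouette criterion compares
partitions on an equal footing and has neither defect. The year is treated
as a line, not a cycle: eleven consecutive pairs, no December--January
wraparound.

```{r}
snaps <- monthly_snapshots(gen$movements)
detect_periods(snaps)
```

Link persistence classes follow fixed activity-month boundaries — backbone
(all 12 months), frequent (7--11), intermediate (3--6), occasional (1--2) —
so `classify_links()` is a deterministic function of activity months, the
four class subnetworks are link-disjoint, and their union reproduces the
annual network exactly. `activity_raster()` exports the links-by-months
activity table behind strip plots.

## QAP correlation

`network_correlation()` computes the Pearson (product-moment) correlation
over the off-diagonal cells of the two weight matrices aligned on the union
node set (diagonals are structural zeros, standard QAP practice; a binary
mode correlates link presence instead of volumes, and both modes coincide on
0/1 weights). `qap_test()` assesses significance with node-label
permutations: the second matrix's rows and columns are permuted jointly by a
uniform random relabelling, 1000 times by default. The p-value uses the
add-one convention $p = (1 + \#\{r_\pi \ge r_{obs}\}) / (n_{perm} + 1)$: it
is never exactly zero, is exact under the permutation null, and counts ties
towards rejection — slightly conservative compared with reporting the raw
fraction of exceeding correlations. Degenerate inputs (a constant
off-diagonal matrix) are an error, since the correlation is undefined.

## Numerical conventions and test scale

* Percentages are computed at full precision and rounded half-up only in the
  explicitly integer-rounded columns.
* Jaccard conventions: both-empty gives 1; weighted comparisons use a
  `>=` with a $10^{-12}$ tolerance where floating-point ties matter (QAP).
* All stochastic functions take explicit seeds; the generator derives its
  entire output from `sim_config()$seed`.

The test suite validates the methods at sizes chosen to keep the whole suite
fast while leaving no stochastic check underpowered: the dominant-flow
decomposition is compared against an exhaustive brute-force implementation
on hundreds of random weighted digraphs of up to 5 nodes; clustering,
diameter and components against brute force on 1,000 digraphs of up to 6
nodes; period and class recovery on 20 replicate synthetic years at the
default conditions; power-law recovery on samples of $10^4$ draws from a
known exponent; and QAP calibration on 200--400 null replicates of 20-node
networks with 199 permutations each.

## Limitations

* The nodal-region decomposition extracts one parent per node; it does not
  build multi-level hierarchies.
* Period detection assumes contiguous periods within a single year; it is
  not a general change-point method and does not model multi-year
  periodicity.
* Distance profiles use great-circle distances, not road or corridor
  distances.
* The power-law machinery fits and diagnoses a single family; it does not
  run likelihood-ratio comparisons against alternative heavy-tailed models.
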