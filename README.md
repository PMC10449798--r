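# pamatch

Probabilistic analogical mapping (PAM) between attributed part graphs, in
R. Given two objects described by labeled parts — 2D keypoints with
externally computed embeddings, or 3D point clouds with per-point
embeddings — `pamatch` infers which part of the target corresponds to each
part of the source, using both part appearance and spatial relations, and
transfers annotations (markers) through the inferred correspondence.

The intended users are computational cognitive scientists and vision
researchers studying zero-shot analogical correspondence: the package
provides the reasoning stack (graph construction, relation embeddings,
inference, decoding, marker transfer, evaluation and response-variability
analysis) and treats the perception stack (image/point encoders) as an
input, with synthetic generators standing in for it during testing.

## The model

An object is an attributed graph: node $i$ has attribute vector
$\mathbf{o}_i$ and coordinates $\mathbf{c}_i$; each ordered node pair
carries a spatial-relation vector $\mathbf{r}_{ij}$ built from three
angular components and range-normalized coordinate differences relative to
the object centroid. A soft correspondence matrix $\mathbf{M}$ is inferred
by maximizing the posterior $p(\mathbf{M}\mid G, G') \propto
p(G, G'\mid\mathbf{M})\,p(\mathbf{M})$ with

$$\log p(G,G'\mid \mathbf{M}) = (1-\alpha)\,
\frac{\sum_{i,j\ne i,i',j'\ne i'} M_{ii'}M_{jj'}\,
\mathrm{sim}(\mathbf{r}_{ij},\mathbf{r}_{i'j'})}{N(N-1)}
+ \alpha\,\frac{\sum_{i,i'} M_{ii'}\,
\mathrm{sim}(\mathbf{o}_i,\mathbf{o}_{i'})}{N},
\qquad
\log p(\mathbf{M}) = \frac{1}{\beta}\sum_{i,i'} M_{ii'}\log M_{ii'},$$

where $\mathrm{sim}$ is cosine similarity, $\alpha$ (default 0.9) weights
node against edge similarity, and the entropy prior favors one-to-one
mappings. Inference is graduated assignment: similarity tensors are
bistochastically pre-normalized, then $\mathbf{M} \leftarrow
\exp(\beta Q)$ / Sinkhorn-balancing iterations anneal $\beta$ from 0.1
upward over 500 (2D) or 200 (3D) iterations; the final per-target argmax
is the decoded mapping. 3D marker transfer picks the target point
minimizing $d_\delta = \frac13(|\Delta d_{local}| + |\Delta d_{global}| +
|\Delta d_{feat}|)$ within the matched cluster.

See `vignettes/analogical-mapping.Rmd` for the full account, including
the Hartigan dip test used in the response-variability analysis.

## A worked example

```r
library(pamatch)

pair <- makeGraphPair(N = 8, sigmaAttr = 0.3, sigmaCoord = 0.05, seed = 7)
res  <- graduatedAssignment(pair$source, pair$target, pamConfig("2d"))
res
#> MappingResult: 8 x 8 mapping, 500 iterations, final beta 168
#>   decoded assignment (target -> source): 1 2 7 8 3 4 6 5
#>   energy: 166.24 -> -0.1695
pairAccuracy(decodedAssignment(res), pair$permutation)
#> [1] 1
```

The decoded assignment lists, for each target part, the source part with
the strongest mapping; here every part of a noisy permuted copy is
recovered (accuracy 1), and the energy trace shows the annealed objective
decreasing to its sharp-mapping value. The same pipeline runs on 3D
objects:

```r
quad  <- makePointObject("quadruped", nPoints = 600, sigmaEmbed = 0.05, seed = 1)
cloud <- clusterPoints(quad$points, quad$embeddings, K = 8, seed = 1)
g     <- graphFromClusters(cloud)
self  <- graduatedAssignment(g, g, pamConfig("3d"))
transferMarker(marker("red", pointCoords(cloud)[1, ]), cloud, cloud, self)$dDelta
#> [1] 0
```

A self-analogy returns the marker's own point exactly ($d_\delta = 0$;
the marker sits on a cloud point whose nearest cluster center is its own
cluster's).

## Command line

A thin CLI over the same functions lives at `inst/cli/pamatch.R`
(installed under `system.file("cli", "pamatch.R", package = "pamatch")`):

```sh
Rscript inst/cli/pamatch.R simulate --graphs --n 10 --out-dir fixtures
Rscript inst/cli/pamatch.R map2d --source fixtures/source.json \
    --target fixtures/target.json --out map.csv
Rscript inst/cli/pamatch.R eval --pred map.csv --truth fixtures/truth.csv \
    --report report.csv
```

Subcommands: `map2d`, `map3d` (PLY + embedding CSV in, transferred
markers out), `simulate {--graphs|--clouds|--placements}`, `eval`. All
flags can also be given as `key=value` lines in a file passed with
`--config`.

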