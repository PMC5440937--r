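# motifRing

Circular sequence logos with intra-motif dependency ribbons, for DNA and
RNA motifs.

## The problem

A classical sequence logo models each motif position independently: letter
stacks show per-position nucleotide frequencies scaled to the position's
information content, and nothing else. But binding sites and structured
RNAs carry *intra-motif dependencies* — statistical associations between
the nucleotide identities at two positions (base-paired stem positions in
a tRNA, coupled positions inside a transcription-factor binding site).
A Cartesian logo has nowhere to put that pairwise information.

motifRing draws the motif on a polar coordinate system instead: one sector
per position arranged anticlockwise around a circle, a WebLogo-style letter
stack in each sector, and chord ribbons across the circle whose width is
proportional to the strength of dependency between the two linked
positions. This is aimed at anyone with a set of aligned motif instances —
ChIP-seq/ChIP-exo binding sites aligned on their motif, an RNA seed
alignment, concatenated splice-element fragments — who wants to see both
composition and coupling in one figure.

## The statistics

Given `N` aligned, equal-length, gap-free sequences:

* **Stack heights.** Position `i`'s height is its information content
  `R_i = log2(4) − (H_i + e_n)` bits, where `H_i` is the Shannon entropy of
  the position's nucleotide frequencies and `e_n = 3/(2·ln2·N)` is the
  small-sample correction (optional, on by default). Pseudocounts
  (0.25 per nucleotide by default) keep frequencies strictly positive.
* **χ² Q statistic.** For positions `i, j`, the 16-cell dinucleotide
  contingency table gives `Q = Σ_k (O_k − E_k)²/E_k` with
  `E_k = N·p_i(a)·p_j(b)` under independence; significance is the upper
  tail of `χ²(m−1)`, `m = 16`. Suited to dependencies between conserved
  positions.
* **Mutual information.** `I(X;Y) = Σ p(x,y) log2[p(x,y)/(p(x)p(y))]` in
  bits. Suited to dependencies between variable positions. Significance
  uses Chebyshev's inequality against a column-permutation null: if the
  observed MI sits `K` null standard deviations above the null mean,
  `P ≤ 1/K²`.
* **Filtering.** Background-level links are removed by p-value threshold,
  by dropping the lower fraction of link values (e.g. the lower 33%), or
  by restricting to the links of one node.

Motifs are serialized in a JSON-Graph format (`id`, `background`,
`pseudocounts`, `nodes` with `index`/`label`/`bit`/`base`/`freq`, `links`
with `source`/`target`/`value`; `background` and `pseudocounts` in
A,T,C,G order), so dependency values pre-computed by any other method can
be drawn too. JASPAR, MEME minimal and TRANSFAC matrices convert to
link-free graphs.

## Worked example

```r
library(motifRing)

# 300 aligned 12-mers with one injected dependent pair (position 9 copies
# position 3 with 10% error); all positions otherwise uniform
aln <- simulateAlignment(L = 12, N = 300,
                         dependentPairs = list(c(3, 9, 0.1)), seed = 42)
aln
#> MotifAlignment: 300 sequences x 12 positions (DNA)
#>   sim_0001  AGGCGCATGGGT
#>   sim_0002  AGGCGAGGGTAG
#>   sim_0003  GCAGTCGTAGGC
#>   ... and 297 more

g <- buildMotifGraph(aln, id = "demo", metric = "mi", B = 200, seed = 1,
                     alpha = 0.05)
motifLinks(g)
#>   source target    value statistic     p_value metric
#> 1      3      9 1.428706  1.428706 5.81657e-05     mi
```

Of the 66 position pairs, exactly the injected pair (3, 9) survives the
`p ≤ 0.05` cut. Its mutual information, 1.43 bits, is what a 90% copy of a
uniform letter should give (2 bits at a perfect copy, 0 at independence);
the Chebyshev bound `1/K²` puts it far above the permutation background.
All stacks sit near 0 bits — every position is uniform, so the motif's
signal here is pure *dependency*, invisible to a classical logo:

```r
writeJsonGraph(g, "demo.json")   # exchange format, exact schema keywords
renderSvg(g, "demo.svg")         # circular logo, ribbon 3 -> 9
```

A shell front end wraps the same pipeline
(`system.file("scripts", "motifring.R", package = "motifRing")`):

```sh
Rscript motifring.R build --fasta sites.fa --metric mi --alpha 0.05 --out sites.json
Rscript motifring.R draw  --graph sites.json --min-percentile 0.33 --out sites.svg
```

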