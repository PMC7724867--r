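# dltrace

Linear-space computation of the **unrestricted Damerau-Levenshtein (DL)
distance** between two character sequences, and reconstruction of an
optimal **edit trace** — the substitutions, insertions, deletions, and
adjacent transpositions that realise it — also in linear space.  The DL
distance is a workhorse for comparing biological sequences (protein,
DNA/RNA) and noisy text; for sequences tens of thousands to millions of
characters long, the classical O(mn)-space algorithm simply does not fit
in memory, which is the problem this package addresses.  It is aimed at
anyone who needs exact DL distances or explicit edit scripts at scales
where quadratic space is prohibitive, and at methods developers who want a
heavily cross-verified reference implementation.

## The method

For `A[1:m]`, `B[1:n]`, let `H[i,j]` be the minimum cost of transforming
`A[1:i]` into `B[1:j]` with costs `S` (substitution), `I` (insertion), `D`
(deletion), `T` (adjacent transposition).  The classical recurrence
(Lowrance-Wagner) takes the minimum of

```
H[i-1,j-1] + c(a_i,b_j)                        substitution
H[i,j-1]   + I                                 insertion
H[i-1,j]   + D                                 deletion
H[k-1,l-1] + (i-k-1)D + T + (j-l-1)I           transposition
```

with `k`/`l` the rightmost earlier occurrences of `b_j` in `A` / `a_i` in
`B`.  The far lookback in the fourth case is why the classical algorithm
stores the whole matrix.  Whenever `2S <= I+D <= 2T` (unit costs qualify),
the transposition case only matters when `a_i != b_j` and
`min(i-k, j-l) = 1`, and the recurrence refines into two branches that
look back at most two rows.  `ls_dl2()` exploits this to run in
`Θ(m+n+s)` working memory (`s` = alphabet size); `strip_dl2()` computes
the identical values in cache-friendly vertical strips.  `ls_trace2()` and
`strip_trace2()` recover an optimal trace by Hirschberg-style divide and
conquer over the passes' final boundary arrays, handling the transposition
lines that straddle the bisection ("center crossings") as explicit cases.
A full-matrix implementation (`lw_full_matrix()`) and a cost-ordered
search over edit sequences (`bfs_dl()`) ship as independent
cross-checks.  See the methods vignette
(`vignettes/dl-linear-space-methods.Rmd`) for the full derivations and
design decisions.

## Worked example

The pair `A = "dafac"`, `B = "fdbbec"`:

```r
library(dltrace)
ls_dl2("dafac", "fdbbec")$distance
#> [1] 4
res <- ls_trace2("dafac", "fdbbec")
res$trace
#> <dl_trace> 5 line(s) for strings of length 5 and 6
#>   (1,2)   (2,3)   (3,4)   (4,5)   (5,6)
trace_to_edit_script(res$trace, encode_pair("dafac", "fdbbec"))
#> <dl_edit_script> 6 operation(s), total cost 4
#>           op  u v u2 v2 char cost
#> 1     insert NA 1 NA NA    f    1
#> 2     retain  1 2 NA NA    d    0
#> 3 substitute  2 3 NA NA    b    1
#> 4 substitute  3 4 NA NA    b    1
#> 5 substitute  4 5 NA NA    e    1
#> 6     retain  5 6 NA NA    c    0
```

The distance is 4: insert `f`, keep `d`, substitute `a->b`, `f->b`,
`a->e`, keep `c`.  Each script row is one operation (`u`/`v` are 1-based
positions in `A`/`B`); the `cost` column sums to the distance, and
applying the script reproduces `B` exactly.  A classical illustration of
the trace formalism for these strings is the trace
`{(1,2),(3,1),(4,3),(5,6)}`, whose crossing balanced pair
`{(1,2),(3,1)}` encodes a transposition of `d` and `f`:

```r
p <- encode_pair("dafac", "fdbbec")
tr <- dl_trace(c(1, 3, 4, 5), c(2, 1, 3, 6), p$m, p$n)
attr(trace_to_edit_script(tr, p), "total_cost")
#> [1] 5
```

— a valid trace of cost 5 (delete `a`, transpose `d`/`f`, substitute,
two inserts, retain), though not an optimal one for these strings.

There is also a command-line interface (`inst/cli/dltrace.R`) with
`dist`, `trace`, `gen`, and `bench` subcommands:

```sh
Rscript inst/cli/dltrace.R dist --a dafac --b fdbbec --algorithm strip2
# 4
```

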