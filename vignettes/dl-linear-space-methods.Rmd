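---
title: "Linear-space Damerau-Levenshtein distance and trace reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear-space Damerau-Levenshtein distance and trace reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dltrace)
```

## The model

The unrestricted Damerau-Levenshtein (DL) distance between strings
$A = a_1 \dots a_m$ and $B = b_1 \dots b_n$ is the minimum total cost of an
edit sequence transforming $A$ into $B$ using four operations:
substitution (cost $S$ when the characters differ, always 0 when they are
equal), insertion ($I$), deletion ($D$), and transposition of two adjacent
characters ($T$).  "Unrestricted" means a transposed pair need not be
adjacent in the original string: the characters between them may be deleted
(and new ones inserted) as part of the same manoeuvre.  This is the variant
that admits a clean dynamic program over prefixes, unlike the "optimal
string alignment" shortcut that forbids edits to touch a transposed pair
again; `lw_full_matrix("CA", "ABC")` returns 2 (swap, then insert) where
the restricted variant would give 3.

With $H_{i,j}$ the distance between $A[1{:}i]$ and $B[1{:}j]$, the
full-matrix recurrence is $H_{i,0} = iD$, $H_{0,j} = jI$, and for
$i, j > 0$ the minimum of

1. $H_{i-1,j-1} + c(a_i, b_j)$                       (substitute / retain),
2. $H_{i,j-1} + I$                                   (insert $b_j$),
3. $H_{i-1,j} + D$                                   (delete $a_i$),
4. $H_{k-1,l-1} + (i-k-1)D + T + (j-l-1)I$           (transpose $a_k, a_i$),

where $k$ is the rightmost occurrence of $b_j$ in $A$ before $i$ and $l$
the rightmost occurrence of $a_i$ in $B$ before $j$; case 4 is skipped when
either does not exist.  Case 4 is what forces the classical algorithm to
keep the whole matrix: $k$ may lie arbitrarily far up.  The recurrence
computes the true minimum edit cost provided $I + D \le 2T$ (otherwise
chains of transpositions could be under-counted); this is the `"lw"` mode
of `validate_cost_model()`.

## The refined recurrence

The package's linear-space algorithms rest on one observation: case 4 can
only win when $a_i \ne b_j$ **and** $\min(i-k,\, j-l) = 1$.  If $a_i = b_j$
the transposition is vacuous, and if both gaps are $\ge 2$ the same cells
can be reached at no greater cost by substitutions and insertions — this is
where $2S \le I + D$ is needed.  Case 4 therefore splits into two slim
branches:

* $j - l = 1$: $H_{k-1,j-2} + (i-k-1)D + T$,
* $i - k = 1$: $H_{i-2,l-1} + (j-l-1)I + T$.

The printed unit-cost forms use $(i-k)$ and $(j-l)$; the weighted forms
above reduce to them when $D = I = T = 1$ and are the ones implemented, so
one code path serves all refined-valid models ($2S \le I+D \le 2T$).
`refined_full_matrix()` and `lw_full_matrix()` are asserted cell-by-cell
equal in the test suite over random weighted models.

Both branches look back at most two rows, which is what makes linear space
possible.  `ls_dl2()` keeps four one-dimensional arrays with the following
meaning while cell $(i, j)$ is being computed:

* `R[q]`: $H_{i,q}$ for $q < j$, $H_{i-2,q}$ for $q \ge j$ (one array does
  double duty two rows apart);
* `R1[q]`: $H_{i-1,q}$;
* `FR[q]`: $H_{k-1,q-2}$ for $k$ the last row seen with $a_k = b_q$ — the
  branch-1 lookback, maintained as matches occur;
* `last_row_id[c]`: the last row whose character is $c$, giving $k$;
  two scalars carry $l$ and $H_{i-2,l-1}$ for branch 2 within the row.

The matrix is augmented with a row and column $-1$ filled with a sentinel
`maxVal`; internally every array has one extra slot so the augmented index
never goes negative.  Working storage is exactly $3(n+2) + s$ array
elements (the value reported in `dp_elements` and audited by a test at
$m = n = 2000$).

**Sentinel arithmetic.**  `maxVal` defaults to
$(m+n+1)\max(S,I,D,T) + 1$, which strictly dominates the trivial upper
bound $mD + nI$ on any reachable cell, and sums of a sentinel plus
operation costs stay far below $2^{53}$, so sentinel-contaminated
candidates lose every comparison without overflow.  A user-supplied
`maxVal` is rejected unless it exceeds $mD + nI$.  All arithmetic is in
doubles; for integer-valued costs every value is an exact sum of inputs,
so equality tests are exact (the backtracking comparisons use a $10^{-9}$
tolerance only to be safe under fractional user costs).

## Strips

`strip_dl2()` computes the same recurrence in `ceiling(n/q)` vertical
strips of `q` columns, left to right, each filled with the row loop above
restricted to the strip.  Three length-$(m+2)$ column arrays carry state
across the boundary: `C[i]` and `C1[i]` hold the last and next-to-last
column of the strips completed so far, and `FC[i]` holds the branch-2
lookback $H_{i-2,l-1}$ for the last matching column $l$ of row $i$.  The
index $l$ itself, entering a strip, depends only on the character $a_i$,
so a length-$s$ per-character last-column array suffices to carry it; the
per-column helper `FR` and the last-row index are rebuilt inside each
strip, since every strip re-sweeps all rows.  The blocking changes memory
traffic, not values: a property test asserts distance equality with
`ls_dl2()` for widths $1, 2, 3, \lceil n/2 \rceil, n$ and that the final
`C`, `C1`, `FC` equal the corresponding full-matrix columns.

`choose_strip_width()` picks the largest `q` whose modeled working set —
$3(q+3)$ strip-local elements plus the $3(m+2)$ column elements, times the
element size — fits a given cache capacity.  The model is a deliberate
simplification (it ignores the input strings and associativity); it is
exposed because the CLI needs a default, and an explicit `q` always
overrides it.

## Traces and edit scripts

A **trace** is a set of lines $(u, v)$ joining positions of $A$ to
positions of $B$, no two lines sharing a $u$ or a $v$.  A line is
*balanced* when $a_u = b_v$; lines $(u_1,v_1)$, $(u_2,v_2)$ *cross* when
$u_1 < u_2$ and $v_1 > v_2$.  Reading a trace as operations: unattached
$A$ positions are deletions, unattached $B$ positions insertions,
unbalanced lines substitutions, and a crossing pair of balanced lines a
transposition whose intervening characters are deleted/inserted.
`trace_to_edit_script()` performs this reading and orders operations left
to right by $B$ coordinate (deletions slot in where their $A$ character
falls), so the script applies in one pass; `apply_edit_script()` checks
coverage of every position of both strings while rebuilding $B$.

Only disjoint crossings among balanced lines are interpretable: a line in
two crossings, or a crossing involving an unbalanced line, has no defined
operation reading, and such traces are rejected rather than guessed at.
The divide-and-conquer algorithms below only ever emit the interpretable
kind, which a property test confirms.

## Divide and conquer

`ls_trace2()` bisects $B$ at $h = \lfloor n/2 \rfloor$ (the floor is the
odd-$n$ convention), runs the linear-space pass forward on
$(B[1{:}h],\, A)$ and backward on the reversed suffixes, and re-indexes
the backward arrays into original coordinates (a single array reversal —
confining all reversal arithmetic to one place).  Because the pass
transforms a $B$-part into $A$-prefixes, its deletions are insertions from
$A$'s point of view: for weighted models the pass swaps $I$ and $D$, using
$d_{S,I,D,T}(A,B) = d_{S,D,I,T}(B,A)$.  An optimal trace then either

* has **no center crossing** — cost $\min_i R^f[i] + R'^f[i+1]$ over the
  split point $i$ in $A$ (`combine_no_cc()`, taken over $0 \le i \le m$ so
  either side may be empty);
* has a center crossing whose $B$ endpoints are the two middle columns —
  cost $\min_{u_1 < u_2} R1^f[u_1-1] + R1'^f[u_2+1] + (u_2-u_1-1)D + T$
  over positions with $a_{u_1} = b_{h+1}$, $a_{u_2} = b_h$
  (`combine_cc_adjacent_b()`; the balance restriction is essential — the
  implied transposition writes $a_{u_2} a_{u_1}$ into the middle of $B$,
  which only reproduces $B$ when balanced — and is part of the
  center-crossing definition; without characters the function degrades to
  the pure arithmetic sweep for testing);
* has a center crossing with $u_2 = u_1 + 1$ — cost
  $FR^f[u_1+1] + FR'^f[u_2-1] + (v_1-v_2-1)I + T$, where $v_2$ is the
  rightmost occurrence of $a_{u_2}$ in $B[1{:}h]$ and $v_1$ the leftmost
  occurrence of $a_{u_1}$ after $h$ (`combine_cc_adjacent_a()`).  The
  index offsets were re-derived rather than trusted: $FR^f[u_1+1]$ keys on
  the character $a_{u_1+1} = a_{u_2}$ and yields
  $d(A[1{:}u_1-1], B[1{:}v_2-1])$; the backward helper lands at reversed
  slot $m-u_2+2$, i.e. original position $u_2-1$.  A test checks the
  combination against a brute-force evaluation from full forward and
  backward matrices.

The cheapest rule wins; ties prefer the clean split, then the
adjacent-in-B crossing, then the adjacent-in-A one, and the smallest index
within a rule — determinism only, any choice is optimal.  At a crossing
split the two lines are recorded immediately and the recursion proceeds on
$A[1{:}u_1-1] \times B[1{:}v_2-1]$ and $A[u_2+1{:}m] \times B[v_1+1{:}n]$;
the skipped characters deliberately stay unattached and surface later as
the transposition's deletions/insertions.

**Base cases.**  Subproblems with $m \le 1$ or $n \le 2$ are solved by a
constant-width full matrix with direct backtracking (preference order:
substitute/retain, delete, insert, transpose).  This sidesteps degenerate
bisections and keeps peak memory linear, since such matrices have $O(m+n)$
cells.

`strip_trace2()` is the same driver with the passes executed by the strip
algorithm.  Run unswapped on $(A\text{-part}, B\text{-part})$, its column
arrays `C`, `C1`, `FC` are already indexed by $A$ positions and play
exactly the roles of `R`, `R1`, `FR`; the two algorithms therefore return
identical traces for every strip width, which is tested directly.

## Independent references

`bfs_dl()` is the package's ground truth for tiny instances: cost-ordered
(Dijkstra-style) search over evolving strings under the four operations,
sharing no recurrence with the dynamic programs.  It uses an admissible,
consistent lower bound — the weighted Levenshtein distance with
substitution cost $\min(S, T/2)$, since one transposition can always be
simulated by two substitutions — so the first goal expansion is optimal.
The search alphabet is the symbols of $A \cup B$: any optimal sequence can
be normalised to a trace, which writes only characters of $B$, so nothing
is lost.  Strings longer than 8 are refused; beyond that the full-matrix
implementations (themselves verified against the search on tiny inputs)
serve as the reference.  `enumerate_center_crossings()` brute-forces the
center-crossing definition on small instances to validate the combiners.

## Synthetic data

`random_sequence()` draws i.i.d. uniform symbols, by default over the 20
amino-acid letters — the random-protein regime these algorithms are
customarily benchmarked in; DNA and arbitrary alphabets are options.  The
generator emulates composition-less random sequences only: no residue
frequency bias, no repeats or homopolymer structure, no evolutionary
relatedness between the pair.  Passing tests therefore demonstrate
correctness of the computation on arbitrary strings (the property suites
also sweep alphabets of size 2 and 4, where transposition opportunities
are dense), not performance claims about any particular biological corpus.

## Problem sizes and test design

The property suites run roughly: 1000 random unit-cost pairs of lengths
0-50 and 200 weighted pairs across all five distance implementations; 500
pairs of length $\le 7$ against the search oracle (plus an exhaustive
sweep of all two-letter strings of length $\le 3$); 500 pairs of length
$\le 40$ through both trace algorithms with full script verification; 300
metric-axiom triples; and a $2000 \times 2000$ allocation audit.  These
sizes exercise every code path (empty strings, single strips, all three
split kinds, weighted models) while keeping the default `R CMD check`-style
run to a couple of minutes on one core.

## Limitations

* The textbook example trace (`{(1,2),(3,1),(4,3),(5,6)}` for
  `dafac` vs `fdbbec`) converts to a script of cost 5, but the distance
  between those strings is 4 — the example trace is a valid, not an
  optimal, trace.  The package's tests treat the search oracle as the
  arbiter of optimality.
* Cost models outside $2S \le I+D \le 2T$ are rejected by the linear-space
  routines; only the full-matrix Lowrance-Wagner path supports the wider
  $I+D \le 2T$ regime, and nothing here supports $I+D > 2T$.
* The trace recursion is orchestrated in R with compiled passes; for the
  megabase-scale comparisons the distance kernels can handle, trace
  reconstruction cost is dominated by the $O(\log n)$ levels of R-level
  recursion bookkeeping, and no multi-core path is provided.
* `bfs_dl()` is intentionally capped at length 8 and exists for
  verification, not production use.
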