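#include <Rcpp.h>
using namespace Rcpp;

// One synchronous-mark, sequential-update sweep of the individual-based
// killing model.  Grid entries: +1 (strain A), -1 (strain B), 0 (empty).
//
// At the start of the step every occupied cell is independently marked
// killer (prob kill_frac) and/or reproducer (prob repro_frac).  The sweep
// then visits sites in row-major order from the top-left corner; a visited
// cell acts only if it is still alive.  A killer empties all 8-neighbours
// of the opposite strain; a reproducer copies itself into one uniformly
// chosen adjacent empty site (aborted when none).  Cells killed earlier in
// the sweep lose their marks; newborns carry no marks until the next step.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() in R fixes
// the trajectory bit-exactly.

static inline int wrap(int i, int n) {
  if (i < 0) return i + n;
  if (i >= n) return i - n;
  return i;
}

// [[Rcpp::export]]
IntegerMatrix ibm_step_cpp(IntegerMatrix grid, double kill_frac,
                           double repro_frac, bool periodic,
                           Nullable<LogicalMatrix> force_killers = R_NilValue,
                           Nullable<LogicalMatrix> force_reproducers = R_NilValue) {
  const int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix g = clone(grid);
  std::vector<unsigned char> killer((size_t)nr * nc, 0);
  std::vector<unsigned char> repro((size_t)nr * nc, 0);

  if (force_killers.isNotNull() || force_reproducers.isNotNull()) {
    // explicit marks (update-rule tests); no RNG used in the mark phase
    if (force_killers.isNotNull()) {
      LogicalMatrix fk(force_killers.get());
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j)
          if (fk(i, j) && g(i, j) != 0) killer[(size_t)i * nc + j] = 1;
    }
    if (force_reproducers.isNotNull()) {
      LogicalMatrix fr(force_reproducers.get());
      for (int i = 0; i < nr; ++i)
        for (int j = 0; j < nc; ++j)
          if (fr(i, j) && g(i, j) != 0) repro[(size_t)i * nc + j] = 1;
    }
  } else {
    // mark phase: row-major visit order so draws are reproducible
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j)
        if (g(i, j) != 0) {
          size_t idx = (size_t)i * nc + j;
          if (unif_rand() < kill_frac) killer[idx] = 1;
          if (unif_rand() < repro_frac) repro[idx] = 1;
        }
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  int nbr_r[8], nbr_c[8];

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      size_t idx = (size_t)i * nc + j;
      int me = g(i, j);
      if (me == 0) continue;  // dead or empty: no action

      int nn = 0;
      for (int k = 0; k < 8; ++k) {
        int ri = i + dr[k], cj = j + dc[k];
        if (periodic) {
          ri = wrap(ri, nr);
          cj = wrap(cj, nc);
        } else if (ri < 0 || ri >= nr || cj < 0 || cj >= nc) {
          continue;
        }
        nbr_r[nn] = ri;
        nbr_c[nn] = cj;
        ++nn;
      }

      if (killer[idx]) {
        for (int k = 0; k < nn; ++k) {
          int ri = nbr_r[k], cj = nbr_c[k];
          if (g(ri, cj) == -me) {
            g(ri, cj) = 0;  // death clears the victim's marks
            size_t vi = (size_t)ri * nc + cj;
            killer[vi] = 0;
            repro[vi] = 0;
          }
        }
      }

      if (repro[idx]) {
        int empties = 0, er[8], ec[8];
        for (int k = 0; k < nn; ++k)
          if (g(nbr_r[k], nbr_c[k]) == 0) {
            er[empties] = nbr_r[k];
            ec[empties] = nbr_c[k];
            ++empties;
          }
        if (empties > 0) {
          int pick = (int)(unif_rand() * empties);
          if (pick == empties) pick = empties - 1;  // guard u == 1 edge
          g(er[pick], ec[pick]) = me;               // newborn: no marks
        }
      }
    }
  }
  return g;
}
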