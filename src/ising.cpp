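#include <Rcpp.h>
using namespace Rcpp;

// Glauber-style single-spin-flip dynamics with the 8-neighbour (Moore)
// Hamiltonian H = (sum of 8 neighbours) * centre.  A flip negates the
// local Hamiltonian, so the energy difference is dE = 2 * H_old (energy
// decreases with alignment).  The move is accepted iff
// exp(-beta * dE) > u with u ~ Uniform[0,1); favourable or neutral moves
// are therefore always accepted.  Periodic boundaries.

static inline int wrap(int i, int n) {
  if (i < 0) return i + n;
  if (i >= n) return i - n;
  return i;
}

static inline int nbr_sum(const IntegerMatrix &s, int i, int j) {
  const int nr = s.nrow(), nc = s.ncol();
  int sum = 0;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      sum += s(wrap(i + di, nr), wrap(j + dj, nc));
    }
  return sum;
}

// [[Rcpp::export]]
List ising_sweep_cpp(IntegerMatrix spins, double beta, int n_attempts) {
  const int nr = spins.nrow(), nc = spins.ncol();
  IntegerMatrix s = clone(spins);
  const double n = (double)nr * nc;
  long flips = 0;

  for (int a = 0; a < n_attempts; ++a) {
    int idx = (int)(unif_rand() * n);
    if (idx >= nr * nc) idx = nr * nc - 1;
    int j = idx / nr, i = idx - j * nr;  // column-major to match R indexing
    int h_old = s(i, j) * nbr_sum(s, i, j);
    double u = unif_rand();
    if (std::exp(-beta * 2.0 * h_old) > u) {
      s(i, j) = -s(i, j);
      ++flips;
    }
  }
  return List::create(_["spins"] = s, _["flips"] = (double)flips);
}
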