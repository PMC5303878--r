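#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the two-strain killing PDE
//   dA/dt = A (r - s(A+B) - aAB B) + d lap A
//   dB/dt = B (r - s(A+B) - aBA A) + d lap B
// and its public-goods extension
//   dA/dt = A (r - c + b S - s(A+B) - alpha B) + d lap A
//   dB/dt = B (r     + b S - s(A+B) - alpha A) + d lap B
//   dS/dt = rho A - lambda S + D lap S
// on a periodic grid with the 5-point Laplacian.  A matrix with a single
// row (or column) degenerates to a 1-D periodic domain.
//
// The good relaxes fast (lambda ~ 100), so its local production/decay term
// is advanced by the exact solution S <- rho A / lambda + (S - rho A/lambda)
// exp(-lambda dt) (operator split with explicit diffusion); dt is then
// limited by the diffusive CFL bound and the ecological rates, not lambda.
//
// Euler undershoots near extinction fronts are clipped at zero and counted.
// Hot loop uses raw buffers and precomputed wrapped neighbour indices.

// [[Rcpp::export]]
List pde_run_cpp(NumericMatrix A0, NumericMatrix B0, Nullable<NumericMatrix> S0,
                 List params, double dx, double dt, int nsteps,
                 bool public_goods) {
  const int nr = A0.nrow(), nc = A0.ncol();
  const size_t n = (size_t)nr * nc;
  std::vector<double> A(A0.begin(), A0.end()), B(B0.begin(), B0.end());
  std::vector<double> An(n), Bn(n), S, Sn;
  const double r = params["r"], s = params["s"];
  const double aAB = params["alpha_ab"], aBA = params["alpha_ba"];
  const double d = params["d"];
  double b = 0, cost = 0, rho = 0, lambda = 0, D = 0, decay = 0;
  if (public_goods) {
    b = as<double>(params["b"]);
    cost = as<double>(params["c"]);
    rho = as<double>(params["rho"]);
    lambda = as<double>(params["lambda"]);
    D = as<double>(params["big_d"]);
    decay = std::exp(-lambda * dt);
    if (S0.isNull()) {
      S.assign(n, 0.0);
    } else {
      NumericMatrix Sm(S0.get());
      S.assign(Sm.begin(), Sm.end());
    }
    Sn.resize(n);
  }
  const double inv_dx2 = 1.0 / (dx * dx);

  // wrapped neighbour offsets (column-major storage: index = i + nr * j)
  std::vector<int> up(nr), down(nr), left(nc), right(nc);
  for (int i = 0; i < nr; ++i) {
    up[i] = (i == 0 ? nr - 1 : i - 1);
    down[i] = (i == nr - 1 ? 0 : i + 1);
  }
  for (int j = 0; j < nc; ++j) {
    left[j] = (j == 0 ? nc - 1 : j - 1);
    right[j] = (j == nc - 1 ? 0 : j + 1);
  }

  long clips = 0;
  for (int step = 0; step < nsteps; ++step) {
    const double *a = A.data(), *bb = B.data(), *sv = public_goods ? S.data() : nullptr;
    double *an = An.data(), *bn = Bn.data(), *sn = public_goods ? Sn.data() : nullptr;
    for (int j = 0; j < nc; ++j) {
      const size_t c0 = (size_t)nr * j;
      const size_t cl = (size_t)nr * left[j], cr = (size_t)nr * right[j];
      for (int i = 0; i < nr; ++i) {
        const size_t k = c0 + i;
        const size_t ku = c0 + up[i], kd = c0 + down[i];
        const size_t kl = cl + i, kr = cr + i;
        const double av = a[k], bv = bb[k], tot = av + bv;
        const double lapA = (a[ku] + a[kd] + a[kl] + a[kr] - 4.0 * av) * inv_dx2;
        const double lapB = (bb[ku] + bb[kd] + bb[kl] + bb[kr] - 4.0 * bv) * inv_dx2;
        double da, db;
        if (public_goods) {
          const double svk = sv[k];
          da = av * (r - cost + b * svk - s * tot - aAB * bv) + d * lapA;
          db = bv * (r + b * svk - s * tot - aBA * av) + d * lapB;
          const double lapS =
              (sv[ku] + sv[kd] + sv[kl] + sv[kr] - 4.0 * svk) * inv_dx2;
          double sd = svk + dt * D * lapS;
          if (sd < 0) { sd = 0; ++clips; }
          sn[k] = sd;  // production/decay applied after A update below
        } else {
          da = av * (r - s * tot - aAB * bv) + d * lapA;
          db = bv * (r - s * tot - aBA * av) + d * lapB;
        }
        double anew = av + dt * da, bnew = bv + dt * db;
        if (anew < 0) { anew = 0; ++clips; }
        if (bnew < 0) { bnew = 0; ++clips; }
        an[k] = anew;
        bn[k] = bnew;
      }
    }
    if (public_goods) {
      for (size_t k = 0; k < n; ++k) {
        const double qss = rho * An[k] / lambda;
        Sn[k] = qss + (Sn[k] - qss) * decay;
      }
      S.swap(Sn);
    }
    A.swap(An);
    B.swap(Bn);
    if ((step + 1) % 200 == 0 || step + 1 == nsteps) {
      bool bad = false;
      for (size_t k = 0; k < n; ++k)
        if (!R_finite(A[k]) || !R_finite(B[k])) { bad = true; break; }
      if (bad)
        stop("non-finite field values by integration step %d; reduce dt",
             step + 1);
    }
  }

  NumericMatrix Aout(nr, nc), Bout(nr, nc);
  std::copy(A.begin(), A.end(), Aout.begin());
  std::copy(B.begin(), B.end(), Bout.begin());
  List out = List::create(_["A"] = Aout, _["B"] = Bout,
                          _["clips"] = (double)clips);
  if (public_goods) {
    NumericMatrix Sout(nr, nc);
    std::copy(S.begin(), S.end(), Sout.begin());
    out["S"] = Sout;
  }
  return out;
}
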