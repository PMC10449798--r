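#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Annealed softassign loop for graduated-assignment mapping inference.
//
// E is the edge compatibility operator with rows/cols indexed by
// column-major vectorized (source, target) node pairs, so E %*% vec(M)
// yields the per-entry edge sums and vec(M)' E vec(M) the quadruple-sum
// edge term of the log-likelihood.  The R wrapper owns all input
// preparation (similarity tensors, bistochastic pre-normalization) and
// interpretation of the result; semantics here must stay in lockstep with
// the exported R operations (compatibility, pamEnergy).

// [[Rcpp::export(name = ".gaLoopCpp")]]
List gaLoopCpp(NumericMatrix E, NumericMatrix nodeSim, double alpha,
               double beta0, double growth, int iterations, int sinkhorn) {
  const int ns = nodeSim.nrow(), nt = nodeSim.ncol();
  const int nv = ns * nt;
  const double qdenom = (ns - 1) + (nt - 1);
  const double edenom = static_cast<double>(ns) * (ns - 1);
  const double colTarget = static_cast<double>(ns) / nt;

  std::vector<double> M(nv, 1.0 / nt), Q(nv), Em(nv), rowmax(ns);
  NumericVector trace(iterations);
  double beta = beta0;

  for (int it = 0; it < iterations; ++it) {
    // compatibility Q = (1 - alpha) * (E %*% m) / qdenom + alpha * nodeSim
    for (int r = 0; r < nv; ++r) {
      double acc = 0.0;
      for (int c = 0; c < nv; ++c) acc += E(r, c) * M[c];
      Q[r] = (1.0 - alpha) * acc / qdenom + alpha * nodeSim[r];
    }
    // M <- exp(beta * (Q - rowmax)), floored so no column can underflow
    // to exact zero (row scalings are absorbed by the balancing)
    for (int i = 0; i < ns; ++i) rowmax[i] = R_NegInf;
    for (int r = 0; r < nv; ++r) {
      const int i = r % ns;
      if (Q[r] > rowmax[i]) rowmax[i] = Q[r];
    }
    for (int r = 0; r < nv; ++r) {
      double e = beta * (Q[r] - rowmax[r % ns]);
      M[r] = std::exp(e < -500.0 ? -500.0 : e);
    }
    // Sinkhorn balancing: columns toward ns/nt, rows to 1 (end on rows)
    for (int s = 0; s < sinkhorn; ++s) {
      for (int j = 0; j < nt; ++j) {
        double cs = 0.0;
        for (int i = 0; i < ns; ++i) cs += M[j * ns + i];
        const double f = colTarget / cs;
        for (int i = 0; i < ns; ++i) M[j * ns + i] *= f;
      }
      for (int i = 0; i < ns; ++i) {
        double rs = 0.0;
        for (int j = 0; j < nt; ++j) rs += M[j * ns + i];
        const double f = 1.0 / rs;
        for (int j = 0; j < nt; ++j) M[j * ns + i] *= f;
      }
    }
    for (int r = 0; r < nv; ++r)
      if (!std::isfinite(M[r]))
        stop("mapping matrix became non-finite at iteration %d", it + 1);
    // energy of the updated M at this iteration's beta
    double quad = 0.0, node = 0.0, ent = 0.0;
    for (int r = 0; r < nv; ++r) {
      double acc = 0.0;
      for (int c = 0; c < nv; ++c) acc += E(r, c) * M[c];
      Em[r] = acc;
    }
    for (int r = 0; r < nv; ++r) {
      quad += M[r] * Em[r];
      node += M[r] * nodeSim[r];
      if (M[r] > 0) ent += M[r] * std::log(M[r]);
    }
    const double ll = (1.0 - alpha) * quad / edenom + alpha * node / ns;
    trace[it] = -ll - ent / beta;
    beta *= growth;
  }

  NumericMatrix Mout(ns, nt);
  std::copy(M.begin(), M.end(), Mout.begin());
  return List::create(_["M"] = Mout, _["trace"] = trace,
                      _["finalBeta"] = beta / growth);
}
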