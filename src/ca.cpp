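#include <Rcpp.h>
using namespace Rcpp;

// Single-cell update, rules applied in order:
//   R1 phenotype switch -> R2 ECM degradation -> R3 biased exclusion move.
// Coordinates are 1-based; phen codes 1 = A, 2 = M; occ holds 0 or cell id.
// All randomness comes from R's RNG so set.seed() governs the whole run.
static inline void update_cell(int i, IntegerMatrix &occ, IntegerVector &r1,
                               IntegerVector &r2, IntegerVector &phen,
                               NumericMatrix &ecm, double alpha, double beta,
                               double cA, double cM, double delta,
                               double kappa, bool switching) {
  const int S1 = occ.nrow(), S2 = occ.ncol();
  const int cr1 = r1[i], cr2 = r2[i];
  double mu = ecm(cr1 - 1, cr2 - 1);

  // R1: A switches with prob alpha*mu, M with prob beta*(1-mu)
  if (switching) {
    double srate = (phen[i] == 1) ? alpha * mu : beta * (1.0 - mu);
    if (unif_rand() < srate) phen[i] = (phen[i] == 1) ? 2 : 1;
  }

  // R2: the (possibly just switched) M-cell degrades its own site
  if (phen[i] == 2 && delta > 0.0) {
    mu *= (1.0 - delta);
    ecm(cr1 - 1, cr2 - 1) = mu;
  }

  // R3: move attempt with sigmoidal, resistance-dependent rate
  double cX = (phen[i] == 1) ? cA : cM;
  double lambda = cX / (1.0 + std::exp(15.0 * (mu - 0.5)));
  if (unif_rand() >= lambda) return;

  // direction weights: right exp(+kappa), left exp(-kappa), up/down 1
  double wl = std::exp(-kappa), wr = std::exp(kappa);
  double u = unif_rand() * (wl + wr + 2.0);
  int t1 = cr1, t2 = cr2;
  if (u < wl) {
    t2 = cr2 - 1;                       // left, toward lower gradient
  } else if (u < wl + wr) {
    t2 = cr2 + 1;                       // right, toward the target column
  } else if (u < wl + wr + 1.0) {
    t1 = (cr1 == S1) ? 1 : cr1 + 1;     // up, periodic wrap
  } else {
    t1 = (cr1 == 1) ? S1 : cr1 - 1;     // down, periodic wrap
  }
  if (t2 < 1 || t2 > S2) return;        // reflecting r2 boundary: abort
  if (occ(t1 - 1, t2 - 1) != 0) return; // exclusion: target occupied
  occ(cr1 - 1, cr2 - 1) = 0;
  occ(t1 - 1, t2 - 1) = i + 1;
  r1[i] = t1;
  r2[i] = t2;
}

// Run n_updates random sequential single-cell updates (n_cells of them
// make one Monte Carlo step). Inputs are cloned, never mutated: the
// updated state components are returned as a list.
// [[Rcpp::export]]
List cpp_run_updates(IntegerMatrix occ_in, IntegerVector r1_in,
                     IntegerVector r2_in, IntegerVector phen_in,
                     NumericMatrix ecm_in, double alpha, double beta,
                     double cA, double cM, double delta, double kappa,
                     bool switching, double n_updates, int forced_cell = 0) {
  IntegerMatrix occ = clone(occ_in);
  IntegerVector r1 = clone(r1_in), r2 = clone(r2_in), phen = clone(phen_in);
  NumericMatrix ecm = clone(ecm_in);
  const int n = r1.size();
  if (forced_cell != 0) {
    if (forced_cell < 1 || forced_cell > n) stop("invalid cell id");
    update_cell(forced_cell - 1, occ, r1, r2, phen, ecm, alpha, beta, cA,
                cM, delta, kappa, switching);
  } else {
    for (double k = 0; k < n_updates; k += 1.0) {
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      update_cell(i, occ, r1, r2, phen, ecm, alpha, beta, cA, cM, delta,
                  kappa, switching);
    }
  }
  return List::create(_["occ"] = occ, _["r1"] = r1, _["r2"] = r2,
                      _["phen"] = phen, _["ecm"] = ecm);
}
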