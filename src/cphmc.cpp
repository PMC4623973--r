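// Constant-pH Metropolis Monte Carlo with optional replica exchange in the
// pH dimension. One "attempt" advances every replica by one move (a site
// flip, or with probability conf_move_prob a conformer move); every
// exchange_interval attempts a sweep over adjacent pH pairs (alternating
// even/odd pairing) swaps pH assignments with probability
// min{1, exp[ln10 (N_i - N_j)(pH_i - pH_j)]}. Uses R's RNG, so runs are
// reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_run_cphmc(NumericVector pka, NumericMatrix shift, NumericVector base_e,
                   List coup, double kT, NumericVector ladder,
                   int n_attempts, double conf_move_prob, int exchange_interval,
                   double burn_in_fraction, int thin, bool do_exchange)
{
  const int ns = pka.size();
  const int nc = base_e.size();
  const int nr = ladder.size();
  const double ln10 = M_LN10;
  const double kTln10 = kT * ln10;

  if (ns > 30) stop("engine supports at most 30 titratable sites");

  std::vector<NumericMatrix> cm;
  cm.reserve(nc);
  for (int c = 0; c < nc; ++c) cm.push_back(as<NumericMatrix>(coup[c]));

  // replica state; start in the lowest-base-energy conformer with each site
  // protonated iff its replica's pH is below the site's reference pKa
  std::vector< std::vector<int> > x(nr, std::vector<int>(ns, 0));
  std::vector<int> conf(nr, 0), N(nr, 0), rep_at_rank(nr);
  std::vector<double> ph_of(nr);
  int c0 = 0;
  for (int c = 1; c < nc; ++c) if (base_e[c] < base_e[c0]) c0 = c;
  for (int r = 0; r < nr; ++r) {
    ph_of[r] = ladder[r];
    rep_at_rank[r] = r;
    conf[r] = c0;
    int n = 0;
    for (int i = 0; i < ns; ++i) { x[r][i] = (ladder[r] < pka[i]) ? 1 : 0; n += x[r][i]; }
    N[r] = n;
  }

  const int burn = (int)std::floor(burn_in_fraction * (double)n_attempts);
  int n_rec_t = 0;
  for (int t = burn + 1; t <= n_attempts; ++t) if ((t - burn) % thin == 0) ++n_rec_t;
  const R_xlen_t total = (R_xlen_t)n_rec_t * nr;
  IntegerVector rec_rep(total), rec_att(total), rec_conf(total), rec_mask(total), rec_N(total);
  NumericVector rec_ph(total);
  const int npair = nr > 1 ? nr - 1 : 0;
  IntegerVector ex_att(npair), ex_acc(npair);

  R_xlen_t k = 0;
  long sweep = 0;
  for (int t = 1; t <= n_attempts; ++t) {
    for (int r = 0; r < nr; ++r) {
      const double ph = ph_of[r];
      const int c = conf[r];
      if (nc > 1 && unif_rand() < conf_move_prob) {
        int cp = (int)(unif_rand() * (nc - 1));
        if (cp >= nc - 1) cp = nc - 2;
        if (cp >= c) ++cp;
        double dE = base_e[cp] - base_e[c];
        for (int i = 0; i < ns; ++i) if (x[r][i]) {
          dE += shift(i, cp) - shift(i, c);
          for (int j = i + 1; j < ns; ++j)
            if (x[r][j]) dE += cm[cp](i, j) - cm[c](i, j);
        }
        if (dE <= 0.0 || unif_rand() < std::exp(-dE / kT)) conf[r] = cp;
      } else {
        int i = (int)(unif_rand() * ns);
        if (i >= ns) i = ns - 1;
        double cost = kTln10 * (ph - pka[i]) + shift(i, c);
        for (int j = 0; j < ns; ++j)
          if (j != i && x[r][j]) cost += cm[c](i, j);
        const double dG = x[r][i] ? -cost : cost;
        if (dG <= 0.0 || unif_rand() < std::exp(-dG / kT)) {
          x[r][i] = 1 - x[r][i];
          N[r] += x[r][i] ? 1 : -1;
        }
      }
    }
    if (do_exchange && nr > 1 && (t % exchange_interval) == 0) {
      ++sweep;
      const int start = (sweep % 2 == 1) ? 0 : 1;
      for (int q = start; q + 1 < nr; q += 2) {
        const int ri = rep_at_rank[q], rj = rep_at_rank[q + 1];
        ex_att[q] += 1;
        const double lp = ln10 * (double)(N[ri] - N[rj]) * (ph_of[ri] - ph_of[rj]);
        if (lp >= 0.0 || unif_rand() < std::exp(lp)) {
          std::swap(ph_of[ri], ph_of[rj]);
          rep_at_rank[q] = rj;
          rep_at_rank[q + 1] = ri;
          ex_acc[q] += 1;
        }
      }
    }
    if (t > burn && (t - burn) % thin == 0) {
      for (int r = 0; r < nr; ++r) {
        rec_rep[k] = r + 1;
        rec_att[k] = t;
        rec_ph[k] = ph_of[r];
        rec_conf[k] = conf[r] + 1;
        int m = 0;
        for (int i = 0; i < ns; ++i) if (x[r][i]) m |= (1 << i);
        rec_mask[k] = m;
        rec_N[k] = N[r];
        ++k;
      }
    }
  }

  return List::create(_["replica"] = rec_rep, _["attempt"] = rec_att,
                      _["pH"] = rec_ph, _["conf"] = rec_conf,
                      _["mask"] = rec_mask, _["N"] = rec_N,
                      _["ex_attempts"] = ex_att, _["ex_accepts"] = ex_acc);
}
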