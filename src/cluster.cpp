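#include <Rcpp.h>
using namespace Rcpp;

// Cross-run occurrence count per feature: number of distinct runs containing a
// feature within ppm_tol (relative to the query mass) and mt_tol (strict, per
// the "lower than" identity rule). Inputs must be sorted by ascending mass.
// run is a 0-based integer run index; n_run its cardinality.
// [[Rcpp::export(name = ".occurrence_counts")]]
IntegerVector occurrence_counts(NumericVector mass, NumericVector mt,
                                IntegerVector run, int n_run,
                                double ppm_tol, double mt_tol) {
  const int n = mass.size();
  IntegerVector out(n);
  std::vector<int> stamp(n_run, -1);
  int lo = 0;
  for (int i = 0; i < n; ++i) {
    const double w = mass[i] * ppm_tol * 1e-6;
    while (lo < n && mass[lo] < mass[i] - w) ++lo;
    int cnt = 0;
    for (int j = lo; j < n && mass[j] < mass[i] + w; ++j) {
      if (std::fabs(mt[j] - mt[i]) < mt_tol && stamp[run[j]] != i) {
        stamp[run[j]] = i;
        ++cnt;
      }
    }
    out[i] = cnt;
  }
  return out;
}

// Greedy reference-based clustering. Features are visited in the given
// processing order (0-based indices, highest priority first). Each unmatched
// feature seeds a master; later features join the nearest master whose SEED
// mass is within ppm_tol (reference = seed mass) and seed time within mt_tol
// (both strict). Nearest = smallest ppm deviation, ties by smaller time gap.
// A master keeps at most one feature per run: the more intense feature stays,
// the displaced one seeds a new master.
// Returns a 0-based master index per feature.
// [[Rcpp::export(name = ".greedy_cluster")]]
IntegerVector greedy_cluster(NumericVector mass, NumericVector mt,
                             NumericVector intensity, IntegerVector run,
                             IntegerVector order, int n_run,
                             double ppm_tol, double mt_tol) {
  const int n = mass.size();
  IntegerVector assign(n, -1);
  std::vector<double> seed_mass, seed_mt;
  std::vector< std::vector<int> > member_of_run;  // per master: run -> feature
  seed_mass.reserve(2048);

  for (int k = 0; k < n; ++k) {
    int f = order[k];
    // repeat so a displaced feature can seed its own master
    while (true) {
      int best = -1;
      double best_ppm = 0, best_dt = 0;
      for (size_t m = 0; m < seed_mass.size(); ++m) {
        double ppm = std::fabs(mass[f] - seed_mass[m]) / seed_mass[m] * 1e6;
        if (ppm >= ppm_tol) continue;
        double dt = std::fabs(mt[f] - seed_mt[m]);
        if (dt >= mt_tol) continue;
        if (best < 0 || ppm < best_ppm ||
            (ppm == best_ppm && dt < best_dt)) {
          best = (int) m;
          best_ppm = ppm;
          best_dt = dt;
        }
      }
      if (best < 0) {
        // seed a new master
        assign[f] = (int) seed_mass.size();
        seed_mass.push_back(mass[f]);
        seed_mt.push_back(mt[f]);
        member_of_run.push_back(std::vector<int>(n_run, -1));
        member_of_run.back()[run[f]] = f;
        break;
      }
      int held = member_of_run[best][run[f]];
      if (held < 0) {
        assign[f] = best;
        member_of_run[best][run[f]] = f;
        break;
      }
      if (intensity[f] > intensity[held]) {
        // f takes the slot; the displaced feature seeds a new master
        assign[f] = best;
        member_of_run[best][run[f]] = f;
        assign[held] = (int) seed_mass.size();
        seed_mass.push_back(mass[held]);
        seed_mt.push_back(mt[held]);
        member_of_run.push_back(std::vector<int>(n_run, -1));
        member_of_run.back()[run[held]] = held;
        break;
      }
      // slot occupied by a more intense feature: f seeds a new master
      assign[f] = (int) seed_mass.size();
      seed_mass.push_back(mass[f]);
      seed_mt.push_back(mt[f]);
      member_of_run.push_back(std::vector<int>(n_run, -1));
      member_of_run.back()[run[f]] = f;
      break;
    }
  }
  return assign;
}
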