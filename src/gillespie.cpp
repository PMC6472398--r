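#include <Rcpp.h>
using namespace Rcpp;

// Stochastic simulation of translation on an ensemble of independent
// single-ribosome transcript copies of one gene.
//
// Copy state: 0 = no ribosome (next reaction is initiation at init_rate,
// placing the A-site on codon 2 with the start codon in the P-site);
// k in [2, n_codons] = A-site on codon k (next reaction is elongation at
// rates[k-1], stepping to k+1, or termination off codon n_codons).
// Every snapshot_interval reactions the A-site codon of every occupied
// copy is recorded into the occupancy histogram.
//
// [[Rcpp::export]]
IntegerVector gillespie_occupancy(int n_codons, NumericVector rates,
                                  double init_rate, int n_steps,
                                  int snapshot_interval, int n_copies) {
  if (n_codons < 2) stop("gene must have at least 2 codons");
  if (rates.size() != n_codons) stop("need one elongation rate per codon");
  if (init_rate <= 0.0) stop("initiation rate must be positive");
  if (snapshot_interval < 1) stop("snapshot interval must be >= 1");
  for (int k = 0; k < n_codons; ++k)
    if (rates[k] <= 0.0) stop("elongation rates must be positive");

  std::vector<int> pos(n_copies, 0);
  std::vector<double> copy_rate(n_copies, init_rate);
  double total = init_rate * n_copies;
  IntegerVector occ(n_codons);

  for (int step = 1; step <= n_steps; ++step) {
    // pick the copy whose reaction fires, proportional to its rate
    double u = R::runif(0.0, total);
    int m = 0;
    double acc = 0.0;
    for (; m < n_copies - 1; ++m) {
      acc += copy_rate[m];
      if (u <= acc) break;
    }
    // fire: initiate, elongate, or terminate
    if (pos[m] == 0) pos[m] = 2;
    else if (pos[m] < n_codons) pos[m] += 1;
    else pos[m] = 0;
    total -= copy_rate[m];
    copy_rate[m] = (pos[m] == 0) ? init_rate : rates[pos[m] - 1];
    total += copy_rate[m];

    if (step % snapshot_interval == 0) {
      for (int i = 0; i < n_copies; ++i)
        if (pos[i] > 0) occ[pos[i] - 1] += 1;
    }
  }
  return occ;
}
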