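#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Metropolis-Hastings over the latent three-group membership vector.
//
// The target is  sum_i logg(i, I_i) + sum_j lgamma(k_j + l_j)  (the
// Dirichlet-multinomial normalising terms that do not depend on I cancel
// in every ratio).  Two proposal kernels, chosen with probability 1/2
// each whenever both are available:
//   relabel  - pick a non-empty group uniformly, a locus in it uniformly,
//              and one of the two alternative labels uniformly;
//   exchange - pick an unordered pair of distinct non-empty groups
//              uniformly, one locus from each uniformly, and swap labels.
// When fewer than two groups are non-empty the relabel move is forced.
//
// RNG draw order per proposal (fixed for reproducibility): move-type
// uniform (consumed only when both kernels are available), group/pair
// index, locus index (one or two), alternative-label index (relabel
// only), acceptance uniform (always consumed).  Uses R's RNG so set.seed
// on the R side makes runs bit-identical.

static inline int unif_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
List mh_chain_cpp(NumericMatrix logg, NumericVector kpar, IntegerVector init,
                  int n_sweeps, int n_burn, int proposals_per_sweep,
                  bool track_states) {
  const int L = logg.nrow();
  if (init.size() != L) stop("init length must match logg rows");
  if (track_states && L > 12) stop("state tracking limited to L <= 12");

  std::vector<int> lab(L);
  std::vector<std::vector<int> > members(3);
  std::vector<int> pos(L);
  int l[3] = {0, 0, 0};
  for (int i = 0; i < L; ++i) {
    int g = init[i];
    if (g < 0 || g > 2) stop("labels must be in {0,1,2}");
    lab[i] = g;
    pos[i] = (int)members[g].size();
    members[g].push_back(i);
    ++l[g];
  }

  // base-3 state index, maintained incrementally when tracking
  std::vector<double> pow3;
  long long state_idx = 0;
  std::vector<double> state_counts;
  if (track_states) {
    long long nstates = 1;
    pow3.resize(L);
    for (int i = 0; i < L; ++i) { pow3[i] = (double)nstates; nstates *= 3; }
    state_counts.assign((size_t)nstates, 0.0);
    for (int i = 0; i < L; ++i) state_idx += (long long)lab[i] * (long long)pow3[i];
  }

  IntegerMatrix freq(L, 3);
  long long accepted = 0, proposed = 0;

  RNGScope scope;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int t = 0; t < proposals_per_sweep; ++t) {
      ++proposed;
      int nonempty[3], G = 0;
      for (int g = 0; g < 3; ++g) if (l[g] > 0) nonempty[G++] = g;

      bool do_exchange = false;
      if (G >= 2) do_exchange = (unif_rand() < 0.5);

      if (!do_exchange) {
        int a = nonempty[unif_index(G)];
        int i = members[a][unif_index(l[a])];
        int alt[2], na = 0;
        for (int g = 0; g < 3; ++g) if (g != a) alt[na++] = g;
        int b = alt[unif_index(2)];

        double dlp = logg(i, b) - logg(i, a)
          + std::log(kpar[b] + l[b]) - std::log(kpar[a] + l[a] - 1.0);
        int Gnew = G - (l[a] == 1 ? 1 : 0) + (l[b] == 0 ? 1 : 0);
        double mf = (G >= 2) ? 0.5 : 1.0;
        double mr = (Gnew >= 2) ? 0.5 : 1.0;
        // the 1/2 alternative-label factors cancel
        double ltr = std::log(mr) - std::log(mf)
          + std::log((double)G) - std::log((double)Gnew)
          + std::log((double)l[a]) - std::log((double)(l[b] + 1));

        double u = unif_rand();
        if (std::log(u) < dlp + ltr) {
          // move locus i from a to b (swap-remove)
          int pi = pos[i], lastv = members[a].back();
          members[a][pi] = lastv; pos[lastv] = pi; members[a].pop_back();
          pos[i] = (int)members[b].size(); members[b].push_back(i);
          lab[i] = b; --l[a]; ++l[b];
          if (track_states) state_idx += (long long)(b - a) * (long long)pow3[i];
          ++accepted;
        }
      } else {
        int npairs = G * (G - 1) / 2;
        int pidx = unif_index(npairs);
        int a = -1, b = -1, c = 0;
        for (int x = 0; x < G && a < 0; ++x)
          for (int y = x + 1; y < G; ++y)
            if (c++ == pidx) { a = nonempty[x]; b = nonempty[y]; break; }
        int i = members[a][unif_index(l[a])];
        int j = members[b][unif_index(l[b])];
        // group sizes unchanged: Hastings ratio is 1
        double dlp = logg(i, b) + logg(j, a) - logg(i, a) - logg(j, b);
        double u = unif_rand();
        if (std::log(u) < dlp) {
          int pi = pos[i], pj = pos[j];
          members[a][pi] = j; pos[j] = pi;
          members[b][pj] = i; pos[i] = pj;
          lab[i] = b; lab[j] = a;
          if (track_states)
            state_idx += (long long)(b - a) * (long long)pow3[i]
                       + (long long)(a - b) * (long long)pow3[j];
          ++accepted;
        }
      }
      if (track_states && sweep >= n_burn) state_counts[(size_t)state_idx] += 1.0;
    }
    if (sweep >= n_burn)
      for (int i = 0; i < L; ++i) freq(i, lab[i]) += 1;
  }

  List out = List::create(
    _["freq"] = freq,
    _["accepted"] = (double)accepted,
    _["proposed"] = (double)proposed,
    _["final_membership"] = IntegerVector(lab.begin(), lab.end()));
  if (track_states) out["state_counts"] = NumericVector(state_counts.begin(), state_counts.end());
  return out;
}
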