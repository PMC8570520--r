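// Proposal/acceptance kernels for the neutral-decay simulator and the
// synthetic-sequence evolver.  Bases are 0..3 (A, C, G, T); the 16 context
// matrices arrive flattened as P[ctx * 16 + cur * 4 + der] with
// ctx = f5 * 4 + f3.  All randomness comes from R's RNG so runs are
// reproducible with set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline int draw_base(const double *row) {
  double u = unif_rand();
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) {
    acc += row[j];
    if (u < acc) return j;
  }
  return 3; // guard against rounding in the cumulative sum
}

static inline int codon_index(const int *s, int ci) {
  return s[3 * ci] * 16 + s[3 * ci + 1] * 4 + s[3 * ci + 2];
}

// Geometric-mean CAI over scorable codons (log-w is NA for excluded codons).
static double cai_of(const std::vector<int> &s, const NumericVector &logw) {
  int nc = (int)s.size() / 3;
  double sum = 0.0;
  int n = 0;
  for (int ci = 0; ci < nc; ++ci) {
    double lw = logw[s[3 * ci] * 16 + s[3 * ci + 1] * 4 + s[3 * ci + 2]];
    if (!ISNAN(lw)) { sum += lw; ++n; }
  }
  if (n == 0) return NA_REAL;
  return std::exp(sum / n);
}

// One simulation replicate: propose context-dependent mutations and accept
// them under the synonymous-only (mode 0) or dN/dS-gated (mode 1) rule,
// recording CAI at every `record_every` accepted mutations.
// [[Rcpp::export]]
List cpp_decay_replicate(IntegerVector seq0, NumericVector P,
                         IntegerVector codon_aa, NumericVector codon_logw,
                         IntegerMatrix acceptable, int mode, double dnds,
                         int n_mut, int record_every, double max_proposals,
                         bool count_proposal_sites) {
  int L = seq0.size();
  if (L < 6 || L % 3 != 0) stop("sequence length must be a multiple of 3, >= 6");
  std::vector<int> s(seq0.begin(), seq0.end());

  int n_check = n_mut / record_every + 1;
  NumericVector cai(n_check);
  cai[0] = cai_of(s, codon_logw);

  IntegerVector site_counts(count_proposal_sites ? L : 1);

  double proposals = 0.0;
  double self_disc = 0.0, stop_disc = 0.0, syn_acc = 0.0;
  double nonsyn_offered = 0.0, nonsyn_acc = 0.0, acc_filtered = 0.0;

  int accepted = 0;
  int n_mutable = L - 2; // positions 2..L-1 (1-based): both neighbours exist
  while (accepted < n_mut) {
    if (proposals >= max_proposals)
      stop("proposal cap reached (%g proposals for %d accepted mutations); "
           "degenerate ancestor or fitness table?", max_proposals, accepted);
    ++proposals;
    int pos = 1 + (int)(unif_rand() * n_mutable);
    if (pos > L - 2) pos = L - 2;
    if (count_proposal_sites) site_counts[pos]++;
    int cur = s[pos];
    int ctx = s[pos - 1] * 4 + s[pos + 1];
    int der = draw_base(&P[ctx * 16 + cur * 4]);
    if (der == cur) { ++self_disc; continue; } // non-mutation: rate variation
    int ci = pos / 3;
    int old_codon = codon_index(s.data(), ci);
    s[pos] = der;
    int new_codon = codon_index(s.data(), ci);
    int new_aa = codon_aa[new_codon];
    bool ok;
    if (new_aa < 0) {               // stop codon: never acceptable
      ok = false; ++stop_disc;
    } else if (new_aa == codon_aa[old_codon]) {
      ok = true; ++syn_acc;         // synonymous: always accepted
    } else if (mode == 0) {
      ok = false;                   // synonymous-only run
    } else {
      if (!acceptable(ci, new_aa)) {
        ok = false; ++acc_filtered; // replacement not observed at this site
      } else {
        ++nonsyn_offered;
        ok = unif_rand() < dnds;    // dN/dS as acceptance probability
        if (ok) ++nonsyn_acc;
      }
    }
    if (!ok) { s[pos] = cur; continue; }
    ++accepted;
    if (accepted % record_every == 0)
      cai[accepted / record_every] = cai_of(s, codon_logw);
  }

  return List::create(
    _["cai"] = cai,
    _["final_seq"] = IntegerVector(s.begin(), s.end()),
    _["proposals"] = proposals,
    _["self_discards"] = self_disc,
    _["stop_discards"] = stop_disc,
    _["syn_accepted"] = syn_acc,
    _["nonsyn_offered"] = nonsyn_offered,
    _["nonsyn_accepted"] = nonsyn_acc,
    _["acceptability_filtered"] = acc_filtered,
    _["site_proposals"] = site_counts);
}

// Neutral forward evolution with the same proposal kernel but no coding
// constraint: run until `n_target` substitutions have been applied.
// [[Rcpp::export]]
List cpp_evolve(IntegerVector seq0, NumericVector P, int n_target,
                double max_proposals) {
  int L = seq0.size();
  if (L < 3) stop("sequence too short to have interior sites");
  std::vector<int> s(seq0.begin(), seq0.end());
  int n_mutable = L - 2;
  double proposals = 0.0;
  int accepted = 0;
  while (accepted < n_target) {
    if (proposals >= max_proposals)
      stop("proposal cap reached while evolving sequence");
    ++proposals;
    int pos = 1 + (int)(unif_rand() * n_mutable);
    if (pos > L - 2) pos = L - 2;
    int cur = s[pos];
    int ctx = s[pos - 1] * 4 + s[pos + 1];
    int der = draw_base(&P[ctx * 16 + cur * 4]);
    if (der == cur) continue;
    s[pos] = der;
    ++accepted;
  }
  return List::create(_["seq"] = IntegerVector(s.begin(), s.end()),
                      _["proposals"] = proposals);
}
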