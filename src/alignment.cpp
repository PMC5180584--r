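#include <Rcpp.h>
using namespace Rcpp;

// Global alignment maximising the number of matched bases with free gaps and
// mismatches (match +1, mismatch/gap 0).  Among alignments with maximal match
// count, the one with the shortest alignment length is taken, so identity =
// matches / alignment length is well defined.  Two rolling rows keep memory
// at O(min side).
static void nw_core(const std::string &a, const std::string &b,
                    int &matches, int &aln_len) {
  const int n = a.size(), m = b.size();
  std::vector<int> Mprev(m + 1), Lprev(m + 1), Mcur(m + 1), Lcur(m + 1);
  for (int j = 0; j <= m; ++j) { Mprev[j] = 0; Lprev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = 0; Lcur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int eq = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? 1 : 0;
      int bm = Mprev[j - 1] + eq, bl = Lprev[j - 1] + 1;   // diagonal
      int um = Mprev[j], ul = Lprev[j] + 1;                // gap in b
      if (um > bm || (um == bm && ul < bl)) { bm = um; bl = ul; }
      int lm = Mcur[j - 1], ll = Lcur[j - 1] + 1;          // gap in a
      if (lm > bm || (lm == bm && ll < bl)) { bm = lm; bl = ll; }
      Mcur[j] = bm; Lcur[j] = bl;
    }
    std::swap(Mprev, Mcur); std::swap(Lprev, Lcur);
  }
  matches = Mprev[m];
  aln_len = Lprev[m];
}

// [[Rcpp::export]]
NumericVector cpp_identity_pair(std::string a, std::string b) {
  if (a.empty() || b.empty())
    stop("sequences must be non-empty");
  int mt, al;
  nw_core(a, b, mt, al);
  return NumericVector::create(_["identity"] = (double)mt / al,
                               _["matches"] = mt, _["aln_len"] = al);
}

// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(CharacterVector queries, CharacterVector refs) {
  const int nq = queries.size(), nr = refs.size();
  NumericMatrix out(nq, nr);
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    if (q.empty()) stop("sequences must be non-empty");
    for (int j = 0; j < nr; ++j) {
      if (rs[j].empty()) stop("sequences must be non-empty");
      int mt, al;
      nw_core(q, rs[j], mt, al);
      out(i, j) = (double)mt / al;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Ungapped overlap merge of a forward read with the reverse-complemented
// mate.  All relative offsets are scored (+1 match, -1 mismatch over the
// overlapping region); the best-scoring offset wins, ties going to the
// longer overlap.  The consensus spans the union of both reads, conflicting
// overlap positions resolved by the higher Phred quality (forward wins ties).
// [[Rcpp::export]]
List cpp_merge_overlap(std::string fwd, std::string rrc,
                       std::string fq, std::string rq) {
  const int lf = fwd.size(), lr = rrc.size();
  if (lf == 0 || lr == 0) stop("reads must be non-empty");
  int best_score = INT_MIN, best_s = 0, best_ov = 0;
  for (int s = -(lr - 1); s <= lf - 1; ++s) {
    // rrc position j sits over fwd position s + j
    int i0 = std::max(0, s), i1 = std::min(lf - 1, s + lr - 1);
    int ov = i1 - i0 + 1;
    if (ov <= 0) continue;
    int sc = 0;
    for (int i = i0; i <= i1; ++i)
      sc += (fwd[i] == rrc[i - s] && fwd[i] != 'N') ? 1 : -1;
    if (sc > best_score || (sc == best_score && ov > best_ov)) {
      best_score = sc; best_s = s; best_ov = ov;
    }
  }
  // consensus over the union, coordinates relative to min(0, best_s)
  int start = std::min(0, best_s);
  int end = std::max(lf - 1, best_s + lr - 1);
  std::string cons, cq;
  cons.reserve(end - start + 1);
  for (int p = start; p <= end; ++p) {
    bool inf = (p >= 0 && p < lf);
    bool inr = (p >= best_s && p - best_s < lr);
    if (inf && inr) {
      char qf = fq[p], qr = rq[p - best_s];
      if (fwd[p] == rrc[p - best_s] || qf >= qr) { cons += fwd[p]; cq += std::max(qf, qr); }
      else { cons += rrc[p - best_s]; cq += qr; }
    } else if (inf) { cons += fwd[p]; cq += fq[p]; }
    else { cons += rrc[p - best_s]; cq += rq[p - best_s]; }
  }
  return List::create(_["score"] = best_score, _["overlap"] = best_ov,
                      _["offset"] = best_s, _["sequence"] = cons,
                      _["quality"] = cq);
}
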