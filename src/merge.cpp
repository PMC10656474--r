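#include <Rcpp.h>
using namespace Rcpp;

// Overlap-merge paired reads. r2rc/q2rc must already be the reverse
// complement of read 2 and its reversed quality string. Candidate overlaps
// are scanned from the largest down to min_overlap; the candidate with the
// lowest mismatch rate wins, ties going to the larger overlap. Disagreeing
// bases in the overlap are resolved by the higher Phred value (tie: read 1).
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2rc, CharacterVector q2rc,
                     int min_overlap, double max_mismatch_rate) {
  int n = r1.size();
  CharacterVector merged(n), mqual(n);
  IntegerVector overlap(n), mism(n);
  LogicalVector ok(n);
  NumericVector meanq(n);

  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(r1[i]);
    std::string qa = as<std::string>(q1[i]);
    std::string b = as<std::string>(r2rc[i]);
    std::string qb = as<std::string>(q2rc[i]);
    int l1 = a.size(), l2 = b.size();
    int max_ov = std::min(l1, l2);
    int best_ov = -1, best_mm = 0;
    double best_rate = 2.0;

    for (int ov = max_ov; ov >= min_overlap && ov >= 1; --ov) {
      int allowed = (int)std::floor(max_mismatch_rate * ov);
      int mm = 0;
      bool bad = false;
      // suffix of a vs prefix of b
      for (int k = 0; k < ov; ++k) {
        if (a[l1 - ov + k] != b[k]) {
          if (++mm > allowed) { bad = true; break; }
        }
      }
      if (bad) continue;
      double rate = ov > 0 ? (double)mm / ov : 0.0;
      if (rate < best_rate) { best_rate = rate; best_ov = ov; best_mm = mm; }
    }

    if (best_ov < 0) {
      merged[i] = NA_STRING; mqual[i] = NA_STRING;
      overlap[i] = 0; mism[i] = 0; ok[i] = false; meanq[i] = NA_REAL;
      continue;
    }

    int ov = best_ov;
    int mlen = l1 + l2 - ov;
    std::string ms(mlen, 'N'), mq(mlen, '!');
    for (int k = 0; k < l1 - ov; ++k) { ms[k] = a[k]; mq[k] = qa[k]; }
    for (int k = 0; k < ov; ++k) {
      int pa = l1 - ov + k;
      if (a[pa] == b[k]) {
        ms[pa] = a[pa];
        mq[pa] = std::max(qa[pa], qb[k]);
      } else if (qb[k] > qa[pa]) {
        ms[pa] = b[k]; mq[pa] = qb[k];
      } else {
        ms[pa] = a[pa]; mq[pa] = qa[pa];
      }
    }
    for (int k = ov; k < l2; ++k) { ms[l1 + k - ov] = b[k]; mq[l1 + k - ov] = qb[k]; }

    double qs = 0;
    for (int k = 0; k < mlen; ++k) qs += (int)mq[k] - 33;
    merged[i] = ms; mqual[i] = mq;
    overlap[i] = ov; mism[i] = best_mm; ok[i] = true;
    meanq[i] = qs / mlen;
  }

  return List::create(_["merged"] = merged, _["quality"] = mqual,
                      _["overlap"] = overlap, _["mismatches"] = mism,
                      _["mean_quality"] = meanq, _["ok"] = ok);
}

// Best ungapped placement of `pattern` in each subject, with the 0-based
// start constrained to [lo[i], hi[i]]. Returns n x 2 matrix
// (best start, mismatches); start -1 when no placement fits the subject.
// Ties are broken toward the smallest offset.
// [[Rcpp::export]]
IntegerMatrix scan_motif_cpp(CharacterVector subjects, std::string pattern,
                             IntegerVector lo, IntegerVector hi) {
  int n = subjects.size();
  int plen = pattern.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    if (subjects[i] == NA_STRING) { out(i, 0) = -1; out(i, 1) = 0; continue; }
    std::string s = as<std::string>(subjects[i]);
    int slen = s.size();
    int best = -1, best_mm = plen + 1;
    int a = lo[i] < 0 ? 0 : lo[i];
    int b = std::min(hi[i], slen - plen);
    for (int off = a; off <= b; ++off) {
      int mm = 0;
      for (int k = 0; k < plen; ++k) {
        if (s[off + k] != pattern[k]) {
          if (++mm >= best_mm) break;
        }
      }
      if (mm < best_mm) { best_mm = mm; best = off; }
    }
    out(i, 0) = best;
    out(i, 1) = best == -1 ? 0 : best_mm;
  }
  return out;
}

// Absorb likely sequencing-error variants into abundant parents. Keys must
// be sorted by count descending. A key i is assigned to the first earlier
// key of identical length with count >= min_ratio * count[i] and Hamming
// distance <= max_mismatch. Returns 1-based parent index, 0 = kept as is.
// [[Rcpp::export]]
IntegerVector collapse_parents_cpp(CharacterVector keys, NumericVector counts,
                                   int max_mismatch, double min_ratio) {
  int n = keys.size();
  IntegerVector parent(n);
  std::vector<std::string> ks(n);
  for (int i = 0; i < n; ++i) ks[i] = as<std::string>(keys[i]);
  for (int i = 1; i < n; ++i) {
    int li = ks[i].size();
    for (int j = 0; j < i; ++j) {
      if (counts[j] < min_ratio * counts[i]) break;  // sorted desc
      if ((int)ks[j].size() != li) continue;
      if (parent[j] != 0) continue;  // only top-level parents absorb
      int mm = 0;
      for (int k = 0; k < li; ++k) {
        if (ks[i][k] != ks[j][k]) {
          if (++mm > max_mismatch) break;
        }
      }
      if (mm <= max_mismatch) { parent[i] = j + 1; break; }
    }
  }
  return parent;
}
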