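#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  case 'N': return 'N'; case 'n': return 'n';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp(as<std::string>(x[i]));
  return out;
}

// [[Rcpp::export(name = ".expected_error_cpp")]]
NumericVector expected_error_cpp(CharacterVector quals, int phred_offset = 33) {
  // EE = sum over bases of 10^(-Q/10)
  double tab[128];
  for (int q = 0; q < 128; ++q) tab[q] = std::pow(10.0, -q / 10.0);
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(quals, i));
    double ee = 0.0;
    for (; *s; ++s) {
      int q = (int)(*s) - phred_offset;
      if (q < 0) q = 0;
      if (q > 127) q = 127;
      ee += tab[q];
    }
    out[i] = ee;
  }
  return out;
}

// Ungapped pair merging: scan all relative offsets of R1 vs revcomp(R2),
// score overlap +1 match / -2 mismatch, keep the best-scoring offset whose
// overlap is long enough and clean enough. Staggered layouts (either read
// overhanging the other's 5' end) reduce the merged read to the overlap.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2, CharacterVector q2,
                     int min_overlap, double max_mismatch_fraction,
                     bool allow_stagger, int qcap = 41, int phred_offset = 33) {
  int n = r1.size();
  CharacterVector mseq(n), mqual(n), status(n);
  for (int i = 0; i < n; ++i) {
    std::string A = as<std::string>(r1[i]);
    std::string Aq = as<std::string>(q1[i]);
    std::string B0 = as<std::string>(r2[i]);
    std::string Bq = as<std::string>(q2[i]);
    if (A.size() != Aq.size() || B0.size() != Bq.size())
      stop("malformed record at index %d: sequence and quality lengths differ", i + 1);
    std::string B = revcomp(B0);
    std::string Bqr(Bq.rbegin(), Bq.rend());
    int n1 = (int)A.size(), n2 = (int)B.size();
    int best_score = -1, best_d = 0, best_o = 0;
    bool found = false;
    for (int d = -(n2 - 1); d <= n1 - 1; ++d) {
      int lo = std::max(0, d);            // overlap start in A coords
      int hi = std::min(n1, d + n2);      // overlap end in A coords
      int o = hi - lo;
      if (o < min_overlap) continue;
      int max_mism = (int)std::floor(max_mismatch_fraction * o);
      int mism = 0;
      bool ok = true;
      for (int p = lo; p < hi; ++p) {
        if (A[p] != B[p - d]) {
          if (++mism > max_mism) { ok = false; break; }
        }
      }
      if (!ok) continue;
      int score = (o - mism) - 2 * mism;
      if (!found || score > best_score) {
        found = true; best_score = score; best_d = d; best_o = o;
      }
    }
    if (!found) {
      mseq[i] = NA_STRING; mqual[i] = NA_STRING; status[i] = "no_overlap";
      continue;
    }
    int d = best_d;
    bool staggered = (d < 0) || (d + n2 < n1);
    if (staggered && !allow_stagger) {
      mseq[i] = NA_STRING; mqual[i] = NA_STRING; status[i] = "stagger_rejected";
      continue;
    }
    int lo = std::max(0, d), hi = std::min(n1, d + n2);
    std::string seq, qual;
    seq.reserve(n1 + n2); qual.reserve(n1 + n2);
    if (!staggered) { // A-only prefix
      seq.append(A, 0, lo);
      qual.append(Aq, 0, lo);
    }
    for (int p = lo; p < hi; ++p) {
      char a = A[p], b = B[p - d];
      int qa = (int)Aq[p] - phred_offset, qb = (int)Bqr[p - d] - phred_offset;
      if (a == b) {
        int q = std::min(qa + qb, qcap);
        seq.push_back(a);
        qual.push_back((char)(q + phred_offset));
      } else {
        int q = qa >= qb ? qa - qb : qb - qa;
        seq.push_back(qa >= qb ? a : b);
        qual.push_back((char)(q + phred_offset));
      }
    }
    if (!staggered) { // B-only suffix
      seq.append(B, hi - d, n2 - (hi - d));
      qual.append(Bqr, hi - d, n2 - (hi - d));
    }
    mseq[i] = seq; mqual[i] = qual; status[i] = "merged";
    (void)best_o;
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual, _["status"] = status);
}

// Locate a primer anchored at a read end, allowing the primer to run off the
// boundary down to min_match_fraction of its length, with mismatch rate
// <= max_error_rate over the aligned part. Returns matched length (0 = not found).
static int match_primer_5p(const std::string& read, const std::string& primer,
                           double min_match_fraction, double max_error_rate) {
  int L = (int)primer.size();
  int min_len = (int)std::ceil(min_match_fraction * L);
  for (int j = 0; j + min_len <= L; ++j) { // read starts at primer base j
    int mlen = L - j;
    if (mlen > (int)read.size()) continue;
    int max_mism = (int)std::floor(max_error_rate * mlen);
    int mism = 0; bool ok = true;
    for (int p = 0; p < mlen; ++p) {
      if (read[p] != primer[j + p] && ++mism > max_mism) { ok = false; break; }
    }
    if (ok) return mlen;
  }
  return 0;
}

static int match_primer_3p(const std::string& read, const std::string& primer_rc,
                           double min_match_fraction, double max_error_rate) {
  int L = (int)primer_rc.size();
  int min_len = (int)std::ceil(min_match_fraction * L);
  int n = (int)read.size();
  for (int mlen = L; mlen >= min_len; --mlen) { // read ends at primer_rc base mlen-1
    if (mlen > n) continue;
    int max_mism = (int)std::floor(max_error_rate * mlen);
    int mism = 0; bool ok = true;
    for (int p = 0; p < mlen; ++p) {
      if (read[n - mlen + p] != primer_rc[p] && ++mism > max_mism) { ok = false; break; }
    }
    if (ok) return mlen;
  }
  return 0;
}

// [[Rcpp::export(name = ".trim_primers_cpp")]]
List trim_primers_cpp(CharacterVector reads, CharacterVector quals,
                      std::string primer_fwd, std::string primer_rev,
                      double min_match_fraction, double max_error_rate) {
  std::string rev_rc = revcomp(primer_rev);
  int n = reads.size();
  CharacterVector iseq(n), iqual(n), status(n);
  bool have_qual = quals.size() == n;
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    int f = match_primer_5p(r, primer_fwd, min_match_fraction, max_error_rate);
    if (f == 0) { iseq[i] = NA_STRING; iqual[i] = NA_STRING; status[i] = "no_fwd_primer"; continue; }
    int b = match_primer_3p(r, rev_rc, min_match_fraction, max_error_rate);
    if (b == 0) { iseq[i] = NA_STRING; iqual[i] = NA_STRING; status[i] = "no_rev_primer"; continue; }
    int start = f, end = (int)r.size() - b;
    if (end < start) { iseq[i] = NA_STRING; iqual[i] = NA_STRING; status[i] = "primer_overlap"; continue; }
    iseq[i] = r.substr(start, end - start);
    if (have_qual && STRING_ELT(quals, i) != NA_STRING) {
      std::string q = as<std::string>(quals[i]);
      iqual[i] = q.substr(start, end - start);
    } else iqual[i] = NA_STRING;
    status[i] = "retained";
  }
  return List::create(_["sequence"] = iseq, _["quality"] = iqual, _["status"] = status);
}

// Build per-read quality strings from a flat logical state vector (TRUE =
// low-quality base); reads are consecutive length-L slices.
// [[Rcpp::export(name = ".qual_strings_cpp")]]
CharacterVector qual_strings_cpp(LogicalVector low_state, int read_length,
                                 int q_high, int q_low, int phred_offset = 33) {
  int total = low_state.size();
  if (total % read_length != 0) stop("state vector length not a multiple of read length");
  int n = total / read_length;
  char ch = (char)(q_high + phred_offset), cl = (char)(q_low + phred_offset);
  CharacterVector out(n);
  std::string buf(read_length, ch);
  for (int i = 0; i < n; ++i) {
    for (int p = 0; p < read_length; ++p)
      buf[p] = low_state[i * read_length + p] ? cl : ch;
    out[i] = buf;
  }
  return out;
}

// Ungapped seed-and-extend local alignment: exact k-mer seeds, two-way
// extension with an x-drop stop, +1 match / -2 mismatch. Best hit by score.
// [[Rcpp::export(name = ".seed_extend_cpp")]]
List seed_extend_cpp(std::string query, std::string subject, int seed_k, double xdrop) {
  int lq = (int)query.size(), ls = (int)subject.size();
  if (lq == 0 || ls == 0) stop("empty sequence");
  if (lq < seed_k) stop("query shorter than seed length");
  List none = List::create(_["score"] = NA_REAL, _["identity"] = NA_REAL,
                           _["coverage"] = NA_REAL, _["q_start"] = NA_INTEGER,
                           _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                           _["s_end"] = NA_INTEGER);
  if (ls < seed_k) return none;
  std::unordered_map<std::string, std::vector<int> > idx;
  idx.reserve(ls);
  for (int j = 0; j + seed_k <= ls; ++j)
    idx[subject.substr(j, seed_k)].push_back(j);

  // per-diagonal rightmost query position already covered by an extension
  std::unordered_map<long, int> covered;
  double best_score = -1;
  int bq0 = 0, bq1 = 0, bs0 = 0, bmatch = 0, balen = 0;
  bool found = false;

  for (int i = 0; i + seed_k <= lq; ++i) {
    auto it = idx.find(query.substr(i, seed_k));
    if (it == idx.end()) continue;
    for (int j : it->second) {
      long diag = (long)j - (long)i;
      auto cv = covered.find(diag);
      if (cv != covered.end() && i < cv->second) continue;
      // extend right from end of seed
      double sc = seed_k, best_r = seed_k * 1.0;
      int qr = i + seed_k, sr = j + seed_k, best_qr = qr;
      while (qr < lq && sr < ls) {
        sc += (query[qr] == subject[sr]) ? 1.0 : -2.0;
        ++qr; ++sr;
        if (sc > best_r) { best_r = sc; best_qr = qr; }
        if (sc < best_r - xdrop) break;
      }
      // extend left from start of seed
      double scl = best_r, best_l = best_r;
      int ql = i, sl = j, best_ql = ql;
      while (ql > 0 && sl > 0) {
        --ql; --sl;
        scl += (query[ql] == subject[sl]) ? 1.0 : -2.0;
        if (scl > best_l) { best_l = scl; best_ql = ql; }
        if (scl < best_l - xdrop) break;
      }
      int q0 = best_ql, q1 = best_qr;        // half-open on query
      int s0 = j - (i - best_ql);
      int alen = q1 - q0;
      int match = 0;
      for (int p = 0; p < alen; ++p) if (query[q0 + p] == subject[s0 + p]) ++match;
      double score = match - 2.0 * (alen - match);
      covered[diag] = std::max(cv == covered.end() ? 0 : cv->second, q1);
      if (!found || score > best_score ||
          (score == best_score && (s0 < bs0 || (s0 == bs0 && q0 < bq0)))) {
        found = true; best_score = score;
        bq0 = q0; bq1 = q1; bs0 = s0; bmatch = match; balen = alen;
      }
    }
  }
  if (!found) return none;
  return List::create(_["score"] = best_score,
                      _["identity"] = (double)bmatch / balen,
                      _["coverage"] = (double)balen / lq,
                      _["q_start"] = bq0, _["q_end"] = bq1,
                      _["s_start"] = bs0, _["s_end"] = bs0 + balen);
}

// Apply substitution errors at given (0-based) flat positions of a character
// matrix stored as concatenated equal-length strings; helper for the read
// simulator so that 500k reads stay fast.
// [[Rcpp::export(name = ".apply_subs_cpp")]]
CharacterVector apply_subs_cpp(CharacterVector seqs, IntegerVector read_idx,
                               IntegerVector pos, CharacterVector new_base) {
  int n = seqs.size();
  std::vector<std::string> out(n);
  for (int i = 0; i < n; ++i) out[i] = as<std::string>(seqs[i]);
  int m = read_idx.size();
  for (int k = 0; k < m; ++k) {
    int i = read_idx[k] - 1;
    int p = pos[k] - 1;
    if (i < 0 || i >= n || p < 0 || p >= (int)out[i].size()) stop("substitution out of range");
    out[i][p] = as<std::string>(new_base[k])[0];
  }
  return wrap(out);
}
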