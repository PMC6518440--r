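#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Base codes: A=0, C=1, G=2, T/U=3, anything else (hard-masked) = 4.
// Code 4 never satisfies any pairing rule, so masked positions are
// unconditional errors.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': case 'U': return 3;
    default:  return 4;
  }
}

// Hoogsteen triple validity for one motif family.
// Motif ids: 0 = TC (pyrimidine, parallel only): C.G, U.A
//            1 = GA (purine, antiparallel only): G.G, A.A
//            2 = GT (mixed, both orientations):  G.G, U.A
// The third strand (RNA) base is matched against the base of the DNA
// strand that carries the purine tract.
static inline bool pair_ok(int motif, int rna, int pur) {
  switch (motif) {
    case 0: return (rna == 1 && pur == 2) || (rna == 3 && pur == 0);
    case 1: return (rna == 2 && pur == 2) || (rna == 0 && pur == 0);
    case 2: return (rna == 2 && pur == 2) || (rna == 3 && pur == 0);
  }
  return false;
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// Reverse complement on codes (A<->T, C<->G, mask stays mask).
static std::vector<int> revcomp_codes(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int c = v[v.size() - 1 - i];
    r[i] = (c == 0) ? 3 : (c == 1) ? 2 : (c == 2) ? 1 : (c == 3) ? 0 : 4;
  }
  return r;
}

struct MotifScan {
  std::vector<int> valid;   // per-position validity along the diagonal
  std::vector<int> E;       // prefix mismatch counts
  std::vector<int> badpre;  // prefix counts of over-long error runs
};

// Exhaustive overlap-allowed enumeration of qualifying triplex windows.
// For every DNA strand and orientation the RNA is slid along the purine
// strand diagonal by diagonal; per start offset the window length is
// grown, jumping directly to the next length at which the mismatch
// allowance floor(L * rate / 100) could cover the mismatches already
// seen. Windows validated by several motif families are deduplicated on
// (rna interval, dna interval, strand, orientation) by merging the
// per-motif length lists, which are sorted by construction.
// [[Rcpp::export(name = ".tpx_scan_cpp")]]
List tpx_scan_cpp(std::string rna, std::string dna,
                  int min_length, double max_error_rate,
                  LogicalVector motif_enabled,    // TC, GA, GT
                  bool parallel_on, bool antiparallel_on,
                  bool terminal_match, bool both_strands,
                  double max_consecutive_errors, double min_guanine_rate,
                  bool count_only) {
  const std::vector<int> A = encode(rna);
  const std::vector<int> Dfwd = encode(dna);
  const int n = (int)A.size(), m = (int)Dfwd.size();

  const bool use_consec = R_finite(max_consecutive_errors);
  const int consec_cap = use_consec ? (int)max_consecutive_errors : 0;
  const bool use_grate = min_guanine_rate > 0;

  long long total = 0;
  std::vector<int> o_rs, o_ds, o_len, o_mask, o_err, o_str, o_ori;

  MotifScan scan[2];
  std::vector<int> Gpre;
  // per-(s0, motif) qualifying windows, sorted by L by construction
  std::vector<std::pair<int, int> > hits[2]; // (L, n_errors)

  for (int strand = 0; strand < 2; ++strand) {
    if (strand == 1 && !both_strands) break;
    const std::vector<int> P = (strand == 0) ? Dfwd : revcomp_codes(Dfwd);
    for (int ori = 0; ori < 2; ++ori) {
      if (ori == 0 && !parallel_on) continue;
      if (ori == 1 && !antiparallel_on) continue;
      // B is the purine strand in the frame where the RNA window is
      // index-aligned: as-is for parallel, reversed for antiparallel.
      std::vector<int> B = P;
      if (ori == 1) std::reverse(B.begin(), B.end());
      int motifs_here[2];
      int n_motifs = 0;
      if (ori == 0) { // parallel: TC, GT
        if (motif_enabled[0]) motifs_here[n_motifs++] = 0;
        if (motif_enabled[2]) motifs_here[n_motifs++] = 2;
      } else {        // antiparallel: GA, GT
        if (motif_enabled[1]) motifs_here[n_motifs++] = 1;
        if (motif_enabled[2]) motifs_here[n_motifs++] = 2;
      }
      if (n_motifs == 0) continue;

      for (int delta = -(n - 1); delta <= m - 1; ++delta) {
        const int i0 = (delta < 0) ? -delta : 0;
        const int j0 = i0 + delta;
        const int len = std::min(n - i0, m - j0);
        if (len < min_length) continue;

        for (int mi = 0; mi < n_motifs; ++mi) {
          const int motif = motifs_here[mi];
          MotifScan& sc = scan[mi];
          sc.valid.assign(len, 0);
          sc.E.assign(len + 1, 0);
          for (int k = 0; k < len; ++k) {
            sc.valid[k] = pair_ok(motif, A[i0 + k], B[j0 + k]) ? 1 : 0;
            sc.E[k + 1] = sc.E[k] + (sc.valid[k] ? 0 : 1);
          }
          if (use_consec) {
            sc.badpre.assign(len + 1, 0);
            int run = 0;
            for (int k = 0; k < len; ++k) {
              run = sc.valid[k] ? 0 : run + 1;
              sc.badpre[k + 1] = sc.badpre[k] + (run > consec_cap ? 1 : 0);
            }
          }
        }
        if (use_grate) {
          Gpre.assign(len + 1, 0);
          for (int k = 0; k < len; ++k)
            Gpre[k + 1] = Gpre[k] + (B[j0 + k] == 2 ? 1 : 0);
        }

        for (int s0 = 0; s0 + min_length <= len; ++s0) {
          for (int mi = 0; mi < n_motifs; ++mi) {
            hits[mi].clear();
            const MotifScan& sc = scan[mi];
            if (terminal_match && !sc.valid[s0]) continue;
            int L = min_length;
            while (s0 + L <= len) {
              const int errs = sc.E[s0 + L] - sc.E[s0];
              const int allow =
                (int)std::floor(L * max_error_rate / 100.0 + 1e-9);
              if (errs <= allow) {
                bool ok = !terminal_match || sc.valid[s0 + L - 1];
                if (ok && use_consec) {
                  const int lo = s0 + consec_cap;
                  if (lo <= s0 + L - 1 &&
                      sc.badpre[s0 + L] - sc.badpre[lo] > 0)
                    ok = false;
                }
                if (ok && use_grate) {
                  const int g = Gpre[s0 + L] - Gpre[s0];
                  if (100.0 * g + 1e-9 < min_guanine_rate * L) ok = false;
                }
                if (ok) hits[mi].push_back(std::make_pair(errs, L));
                ++L;
              } else {
                if (max_error_rate <= 0) break;
                // smallest L with floor(L * rate / 100) >= errs
                int Lnext =
                  (int)std::ceil(100.0 * errs / max_error_rate - 1e-9);
                L = (Lnext <= L) ? L + 1 : Lnext;
              }
            }
          }

          // merge the per-motif length lists (union of windows)
          size_t ia = 0, ib = 0;
          const size_t na = hits[0].size();
          const size_t nb = (n_motifs == 2) ? hits[1].size() : 0;
          while (ia < na || ib < nb) {
            int L, errs, mask;
            if (ib >= nb ||
                (ia < na && hits[0][ia].second < hits[1][ib].second)) {
              L = hits[0][ia].second;
              errs = hits[0][ia].first;
              mask = 1 << motifs_here[0];
              ++ia;
            } else if (ia >= na || hits[1][ib].second < hits[0][ia].second) {
              L = hits[1][ib].second;
              errs = hits[1][ib].first;
              mask = 1 << motifs_here[1];
              ++ib;
            } else { // same window under both motifs
              L = hits[0][ia].second;
              errs = std::min(hits[0][ia].first, hits[1][ib].first);
              mask = (1 << motifs_here[0]) | (1 << motifs_here[1]);
              ++ia; ++ib;
            }
            ++total;
            if (!count_only) {
              const int jB = j0 + s0;
              const int jP = (ori == 0) ? jB : (m - jB - L);
              o_rs.push_back(i0 + s0);
              o_ds.push_back(strand == 0 ? jP : (m - jP - L));
              o_len.push_back(L);
              o_mask.push_back(mask);
              o_err.push_back(errs);
              o_str.push_back(strand);
              o_ori.push_back(ori);
            }
          }
        }
      }
    }
  }

  if (count_only)
    return List::create(Named("count") = (double)total);

  const int N = (int)o_rs.size();
  IntegerVector rs(N), re(N), ds(N), de(N), mm(N), ne(N);
  CharacterVector st(N), ori(N);
  for (int i = 0; i < N; ++i) {
    rs[i] = o_rs[i];
    re[i] = o_rs[i] + o_len[i];
    ds[i] = o_ds[i];
    de[i] = o_ds[i] + o_len[i];
    mm[i] = o_mask[i];
    ne[i] = o_err[i];
    st[i] = o_str[i] == 0 ? "+" : "-";
    ori[i] = o_ori[i] == 0 ? "parallel" : "antiparallel";
  }
  return List::create(
    Named("count") = (double)total,
    Named("rna_start") = rs, Named("rna_end") = re,
    Named("dna_start") = ds, Named("dna_end") = de,
    Named("dna_strand") = st, Named("orientation") = ori,
    Named("motif_mask") = mm, Named("n_errors") = ne);
}
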