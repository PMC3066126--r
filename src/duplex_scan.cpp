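// Exhaustive ungapped antiparallel scan of miRNAs over transcripts.
//
// Every window of length |miRNA| on each transcript is scored with the
// positional duplex rules. Scores are kept as integers (mismatch = 2,
// wobble = 1, in half-mismatch units doubled; energies in
// decikilocalories) so window verdicts are exact and identical to the
// per-pair R reference implementation.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
    default: return -1;
  }
}

static inline int pair_idx(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 3 && b == 0) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

// [[Rcpp::export]]
DataFrame cpp_scan_targets(CharacterVector mirnas, CharacterVector mirna_ids,
                           CharacterVector transcripts,
                           CharacterVector transcript_ids,
                           IntegerMatrix stack, bool strict,
                           int max_score2, int strict_score2,
                           int region_score2_max, double energy_ratio) {
  std::vector<std::string> out_mir, out_tx;
  std::vector<int> out_start, out_end, out_score2, out_dup, out_per;
  std::vector<bool> out_strict;

  int n_mir = mirnas.size();
  std::vector<std::string> mseq(n_mir);
  std::vector<std::vector<int> > mcode(n_mir);
  std::vector<int> perfect_dc(n_mir, 0);
  for (int m = 0; m < n_mir; ++m) {
    mseq[m] = as<std::string>(mirnas[m]);
    int L = (int)mseq[m].size();
    mcode[m].resize(L);
    for (int i = 0; i < L; ++i) mcode[m][i] = base_code(mseq[m][i]);
    // perfect complement: every position is the Watson-Crick pair of the
    // miRNA base; pair ids depend on the miRNA base alone
    int per = 0;
    std::vector<int> pp(L);
    for (int i = 0; i < L; ++i) {
      int b = mcode[m][i];
      pp[i] = (b == 0) ? 1 : (b == 1) ? 2 : (b == 2) ? 3 : (b == 3) ? 4 : 0;
    }
    for (int i = 0; i + 1 < L; ++i)
      if (pp[i] > 0 && pp[i + 1] > 0) per += stack(pp[i] - 1, pp[i + 1] - 1);
    perfect_dc[m] = per;
  }

  for (int t = 0; t < transcripts.size(); ++t) {
    std::string tseq = as<std::string>(transcripts[t]);
    int n = (int)tseq.size();
    std::vector<int> tcode(n);
    for (int i = 0; i < n; ++i) tcode[i] = base_code(tseq[i]);
    for (int m = 0; m < n_mir; ++m) {
      int L = (int)mcode[m].size();
      if (L < 12 || L > n) continue;
      std::vector<int> pidx(L), sc2(L);
      for (int w = 0; w + L <= n; ++w) {
        int total2 = 0;
        // miRNA position i (0-based from 5') faces site base w + L-1-i
        for (int i = 0; i < L; ++i) {
          int p = pair_idx(mcode[m][i], tcode[w + L - 1 - i]);
          pidx[i] = p;
          sc2[i] = (p == 0) ? 2 : (p >= 5) ? 1 : 0;
          total2 += sc2[i];
        }
        if (total2 > max_score2) continue;                       // rule 1
        bool ok = true;
        int run = 0;
        for (int i = 0; i < L && ok; ++i) {                      // rule 2
          run = (sc2[i] == 2) ? run + 1 : 0;
          if (run > 2) ok = false;
        }
        if (!ok) continue;
        for (int i = 1; i < 11 && ok; ++i)                       // rule 3
          if (sc2[i] == 2 && sc2[i + 1] == 2) ok = false;        // pos 2..12
        if (!ok) continue;
        if (sc2[9] == 2 || sc2[10] == 2) continue;               // rule 4
        int region2 = 0;                                         // rule 5
        for (int i = 0; i < 12; ++i) region2 += sc2[i];
        if (region2 > region_score2_max) continue;
        int dup = 0;                                             // rule 6
        for (int i = 0; i + 1 < L; ++i)
          if (pidx[i] > 0 && pidx[i + 1] > 0)
            dup += stack(pidx[i] - 1, pidx[i + 1] - 1);
        if (dup > 0) continue;
        if ((double)(-dup) < energy_ratio * (double)(-perfect_dc[m])) continue;
        bool strict_pass = total2 <= strict_score2;
        if (strict && !strict_pass) continue;
        out_mir.push_back(as<std::string>(mirna_ids[m]));
        out_tx.push_back(as<std::string>(transcript_ids[t]));
        out_start.push_back(w);
        out_end.push_back(w + L);
        out_score2.push_back(total2);
        out_dup.push_back(dup);
        out_per.push_back(perfect_dc[m]);
        out_strict.push_back(strict_pass);
      }
    }
  }
  return DataFrame::create(
    _["mirna_id"] = out_mir, _["transcript_id"] = out_tx,
    _["start"] = out_start, _["end"] = out_end,
    _["score2"] = out_score2, _["duplex_dc"] = out_dup,
    _["perfect_dc"] = out_per, _["strict_pass"] = out_strict,
    _["stringsAsFactors"] = false);
}
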