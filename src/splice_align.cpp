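// Splice-aware local alignment of a transcript against a genomic window.
//
// Three-state affine dynamic program in the est2genome tradition: a
// match/mismatch state with affine short gaps, plus an intron state that
// jumps the genome (never the transcript) at a fixed penalty, reduced when
// the skipped genomic segment is flanked by GT...AG. Local semantics
// (scores floored at zero) so poly-A tails and vector ends soft-clip
// naturally. Terminal blocks shorter than `min_anchor` transcript bases are
// trimmed after traceback: an unanchored micro-exon at the alignment edge
// is indistinguishable from a chance match beyond a spurious intron.
//
// The full match-state score matrix is kept (int16), alongside a one-byte
// traceback code per cell; gap runs and intron openings are re-derived
// from the stored match scores during traceback, which keeps memory at
// three bytes per cell.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const int NEG = -30000;

// [[Rcpp::export(name = ".spliceAlignCpp")]]
List spliceAlignCpp(std::string tseq, std::string gseq,
                    int match, int mismatch, int gap_open, int gap_ext,
                    int intron_penalty, int splice_bonus, int min_intron,
                    int min_anchor = 16) {
  const int m = (int)tseq.size();
  const int n = (int)gseq.size();
  IntegerMatrix noBlocks(0, 4);
  colnames(noBlocks) = CharacterVector::create("gstart", "gend", "tstart",
                                               "tend");
  List emptyRes = List::create(_["score"] = 0, _["blocks"] = noBlocks,
                               _["matches"] = 0, _["mismatches"] = 0,
                               _["gaps"] = 0, _["aligned_t"] = 0);
  if (m < 1 || n < 1) return emptyRes;
  const double cells = (double)(m + 1) * (double)(n + 1);
  if (cells > 8e8)
    stop("alignment window too large (%d x %d)", m, n);

  const char *t = tseq.c_str();
  const char *g = gseq.c_str();

  std::vector<int16_t> M((size_t)(m + 1) * (n + 1), (int16_t)NEG);
  std::vector<uint8_t> TB((size_t)(m + 1) * (n + 1), 0);
  auto midx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  std::vector<int> prevIx(n + 1, NEG), curIx(n + 1, NEG);
  std::vector<int> prevIy(n + 1, NEG), curIy(n + 1, NEG);

  int best = 0, bi = -1, bj = -1;

  for (int i = 1; i <= m; ++i) {
    int runAny = NEG, runGT = NEG;
    std::fill(curIx.begin(), curIx.end(), NEG);
    std::fill(curIy.begin(), curIy.end(), NEG);
    const int16_t *Mprev = &M[midx(i - 1, 0)];
    int16_t *Mcur = &M[midx(i, 0)];
    uint8_t *TBcur = &TB[midx(i, 0)];
    const char ti = t[i - 1];
    for (int j = 1; j <= n; ++j) {
      // newly available intron opening j0 = j - 1 - min_intron
      int j0 = j - 1 - min_intron;
      if (j0 >= 1) {
        int cand = Mprev[j0];
        if (cand > runAny) runAny = cand;
        if (j0 + 1 < n && g[j0] == 'G' && g[j0 + 1] == 'T' && cand > runGT)
          runGT = cand; // donor at genome positions j0+1, j0+2 (1-based)
      }
      int C = NEG;
      if (runAny > NEG) C = runAny + intron_penalty;
      if (runGT > NEG && j >= 3 && g[j - 3] == 'A' && g[j - 2] == 'G') {
        int cg = runGT + intron_penalty + splice_bonus;
        if (cg > C) C = cg;
      }
      int ixo = (Mprev[j] > NEG / 2) ? Mprev[j] + gap_open : NEG;
      int ixe = (prevIx[j] > NEG / 2) ? prevIx[j] + gap_ext : NEG;
      curIx[j] = ixo > ixe ? ixo : ixe;
      int iyo = (Mcur[j - 1] > NEG / 2) ? Mcur[j - 1] + gap_open : NEG;
      int iye = (curIy[j - 1] > NEG / 2) ? curIy[j - 1] + gap_ext : NEG;
      curIy[j] = iyo > iye ? iyo : iye;

      const char gj = g[j - 1];
      int s = (ti == gj && ti != 'N') ? match : mismatch;
      int bestPrev = 0; uint8_t code = 0;
      int16_t dM = Mprev[j - 1];
      if (dM > bestPrev) { bestPrev = dM; code = 1; }
      if (prevIx[j - 1] > bestPrev) { bestPrev = prevIx[j - 1]; code = 2; }
      if (prevIy[j - 1] > bestPrev) { bestPrev = prevIy[j - 1]; code = 3; }
      if (C > bestPrev) { bestPrev = C; code = 4; }
      int val = s + bestPrev;
      if (val < NEG) val = NEG;
      Mcur[j] = (int16_t)val;
      TBcur[j] = code;
      if (val > best) { best = val; bi = i; bj = j; }
    }
    std::swap(prevIx, curIx);
    std::swap(prevIy, curIy);
  }

  if (best <= 0 || bi < 0) return emptyRes;

  // ---- traceback with per-block bookkeeping (blocks in reverse order) ----
  std::vector<int> bG0, bG1, bT0, bT1, bMatch, bMis, bGap, bScore;
  std::vector<int> intronCostAfter; // cost of the intron following block k
  int curMatch = 0, curMis = 0, curGap = 0, curScore = 0;
  int i = bi, j = bj;
  int blkGend = j, blkTend = i;
  auto closeBlock = [&](int gs, int ts) {
    bG0.push_back(gs); bG1.push_back(blkGend);
    bT0.push_back(ts); bT1.push_back(blkTend);
    bMatch.push_back(curMatch); bMis.push_back(curMis);
    bGap.push_back(curGap); bScore.push_back(curScore);
    curMatch = curMis = curGap = curScore = 0;
  };
  for (;;) {
    bool isM = (t[i - 1] == g[j - 1] && t[i - 1] != 'N');
    if (isM) { ++curMatch; curScore += match; }
    else { ++curMis; curScore += mismatch; }
    uint8_t code = TB[midx(i, j)];
    if (code == 0) {
      closeBlock(j, i);
      break;
    } else if (code == 1) {
      --i; --j;
    } else if (code == 2) {
      // gap in genome at (i-1, j-1): Ix(i', j') = M(i'-l, j') + open + (l-1)ext
      int ip = i - 1, jp = j - 1;
      int target = NEG, bl = 1;
      for (int l = 1; l <= ip - 1; ++l) {
        int v = M[midx(ip - l, jp)];
        if (v <= NEG / 2) continue;
        int sc = v + gap_open + (l - 1) * gap_ext;
        if (sc > target) { target = sc; bl = l; }
      }
      curGap += bl;
      curScore += gap_open + (bl - 1) * gap_ext;
      i = ip - bl; j = jp;
    } else if (code == 3) {
      // gap in transcript at (i-1, j-1)
      int ip = i - 1, jp = j - 1;
      int target = NEG, bl = 1;
      for (int l = 1; l <= jp - 1; ++l) {
        int v = M[midx(ip, jp - l)];
        if (v <= NEG / 2) continue;
        int sc = v + gap_open + (l - 1) * gap_ext;
        if (sc > target) { target = sc; bl = l; }
      }
      curGap += bl;
      curScore += gap_open + (bl - 1) * gap_ext;
      i = ip; j = jp - bl;
    } else { // intron closure ending at genome j-1
      int ip = i - 1, jEnd = j - 1;
      bool accAG = (jEnd >= 2 && g[jEnd - 2] == 'A' && g[jEnd - 1] == 'G');
      int target = NEG, bj0 = -1, bcost = intron_penalty;
      for (int j0 = 1; j0 <= jEnd - min_intron; ++j0) {
        int v = M[midx(ip, j0)];
        if (v <= NEG / 2) continue;
        int cost = intron_penalty;
        if (accAG && j0 + 1 < n && g[j0] == 'G' && g[j0 + 1] == 'T')
          cost += splice_bonus;
        int sc = v + cost;
        if (sc >= target) { target = sc; bj0 = j0; bcost = cost; }
      }
      closeBlock(j, i);
      intronCostAfter.push_back(bcost); // intron preceding the closed block
      i = ip; j = bj0;
      blkGend = j; blkTend = i;
    }
  }

  // reorder ascending (transcript/genome order); intronCostAfter[k] in the
  // reversed vectors is the intron before reversed-block k, i.e. after
  // ascending-block (nb-2-k)
  int nb = (int)bG0.size();
  std::vector<int> idx(nb);
  for (int k = 0; k < nb; ++k) idx[k] = nb - 1 - k;

  // trim unanchored terminal blocks
  int lo = 0, hi = nb - 1;
  int score = best;
  auto blockWidth = [&](int k) { return bT1[idx[k]] - bT0[idx[k]] + 1; };
  while (lo < hi && blockWidth(lo) < min_anchor) {
    score -= bScore[idx[lo]];
    // intron after ascending block lo = intronCostAfter[nb - 2 - lo]
    score -= intronCostAfter[nb - 2 - lo];
    ++lo;
  }
  while (hi > lo && blockWidth(hi) < min_anchor) {
    score -= bScore[idx[hi]];
    score -= intronCostAfter[nb - 1 - hi];
    --hi;
  }

  int kept = hi - lo + 1;
  IntegerMatrix blocks(kept, 4);
  int matches = 0, mismatches = 0, gaps = 0, alignedT = 0;
  for (int k = lo; k <= hi; ++k) {
    int r = idx[k];
    int row = k - lo;
    blocks(row, 0) = bG0[r];
    blocks(row, 1) = bG1[r];
    blocks(row, 2) = bT0[r];
    blocks(row, 3) = bT1[r];
    matches += bMatch[r]; mismatches += bMis[r]; gaps += bGap[r];
    alignedT += bT1[r] - bT0[r] + 1;
  }
  colnames(blocks) = CharacterVector::create("gstart", "gend", "tstart", "tend");
  if (score < 0) score = 0;
  return List::create(_["score"] = score, _["blocks"] = blocks,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gaps"] = gaps, _["aligned_t"] = alignedT);
}
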