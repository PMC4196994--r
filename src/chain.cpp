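// Metropolis block sampler over secondary-structure annotations.
// Consumes per-segment log-likelihood matrices and per-position
// log-prior terms precomputed in R, so Hastings ratios are evaluated
// locally on the affected segments in O(1).

#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Constraints {
  int minLen[4];
  bool forbid[4][4];
  int termIdx;  // 0-based state index, -1 for none
};

inline int uniformInt(int n) {  // 0 .. n-1, via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct State {
  std::vector<int> ty;      // 0=H 1=E 2=T 3=C
  std::vector<int> len;
  std::vector<double> bll;  // per-block log-likelihood
  std::vector<double> bpr;  // per-block prior contribution
  double curLL = 0.0, curPR = 0.0;
};

class Sampler {
public:
  int L;
  std::vector<NumericMatrix> seg;      // 4 L x L matrices (H,E,T,C)
  std::vector<std::vector<double> > priorCum;  // per type, cumsum of logq
  Constraints cc;
  bool resample;

  double segLL(int t, int s, int e) const { return seg[t](s - 1, e - 1); }
  double segPR(int t, int s, int e) const {
    return priorCum[t][e] - priorCum[t][s - 1];
  }

  bool valid(const std::vector<int>& ty, const std::vector<int>& len) const {
    int M = ty.size();
    if (cc.termIdx >= 0 && (ty[0] != cc.termIdx || ty[M - 1] != cc.termIdx))
      return false;
    for (int i = 0; i < M; ++i)
      if (len[i] < cc.minLen[ty[i]]) return false;
    for (int i = 0; i + 1 < M; ++i)
      if (cc.forbid[ty[i]][ty[i + 1]]) return false;
    return true;
  }

  static bool anyLong(const std::vector<int>& len) {
    for (size_t i = 0; i < len.size(); ++i)
      if (len[i] >= 2) return true;
    return false;
  }

  // number of feasible move kinds (switch always feasible)
  int nFeas(int M, bool hasLong) const {
    return 1 + (M >= 2 ? 2 : 0) + (hasLong ? 1 : 0);
  }
  double kindLogP(int M, bool hasLong) const {
    return resample ? -std::log((double)nFeas(M, hasLong)) : -std::log(4.0);
  }
};

std::string stateKey(const std::vector<int>& ty, const std::vector<int>& len) {
  static const char code[5] = "HETC";
  std::string s;
  for (size_t i = 0; i < ty.size(); ++i) {
    s += code[ty[i]];
    s += std::to_string(len[i]);
  }
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".chain_run")]]
List chain_run(List segList, NumericMatrix logq, IntegerVector minLen,
               LogicalMatrix forbid, int termIdx, IntegerVector initTy,
               IntegerVector initLen, int nProposals, int burnin, int thin,
               bool resampleInfeasible, bool trackStates, int keepEvery,
               int maxStates) {
  Sampler S;
  S.L = logq.nrow();
  for (int t = 0; t < 4; ++t) S.seg.push_back(as<NumericMatrix>(segList[t]));
  S.priorCum.assign(4, std::vector<double>(S.L + 1, 0.0));
  for (int t = 0; t < 4; ++t)
    for (int p = 1; p <= S.L; ++p)
      S.priorCum[t][p] = S.priorCum[t][p - 1] + logq(p - 1, t);
  for (int t = 0; t < 4; ++t) {
    S.cc.minLen[t] = minLen[t];
    for (int u = 0; u < 4; ++u) S.cc.forbid[t][u] = forbid(t, u);
  }
  S.cc.termIdx = termIdx;  // already 0-based or -1
  S.resample = resampleInfeasible;

  State st;
  st.ty = std::vector<int>(initTy.begin(), initTy.end());
  st.len = std::vector<int>(initLen.begin(), initLen.end());
  {
    int s = 1;
    for (size_t b = 0; b < st.ty.size(); ++b) {
      int e = s + st.len[b] - 1;
      st.bll.push_back(S.segLL(st.ty[b], s, e));
      st.bpr.push_back(S.segPR(st.ty[b], s, e));
      st.curLL += st.bll.back();
      st.curPR += st.bpr.back();
      s = e + 1;
    }
  }

  // accumulators
  NumericMatrix marg(S.L, 4);
  std::map<int, double> mTotal;
  std::map<int, double> mByType[4];
  std::map<std::string, double> freq;
  bool freqOverflow = false;
  std::vector<double> trace;
  long nAccept = 0, nValid = 0, nResampled = 0, nInfeasibleRejected = 0;
  double bestLP = R_NegInf;
  std::vector<int> bestTy, bestLen;
  long bestIter = -1;
  std::vector<std::vector<int> > sampTy, sampLen;

  std::vector<int> nty, nlen;      // candidate scratch

  for (int iter = 1; iter <= nProposals; ++iter) {
    int M = st.ty.size();
    bool hasLong = Sampler::anyLong(st.len);
    // ---- choose a move kind ----
    int kind;  // 0 switch, 1 boundary, 2 split, 3 merge
    bool feas[4] = {true, M >= 2, hasLong, M >= 2};
    if (resampleInfeasible) {
      int nf = S.nFeas(M, hasLong);
      int r = uniformInt(nf);
      kind = 0;
      for (int k = 0; k < 4; ++k) {
        if (!feas[k]) continue;
        if (r == 0) { kind = k; break; }
        --r;
      }
      // count how many kinds were effectively unavailable this draw
      if (nf < 4) ++nResampled;
    } else {
      kind = uniformInt(4);
      if (!feas[kind]) { ++nInfeasibleRejected; goto accumulate; }
    }

    {
      nty = st.ty; nlen = st.len;
      double lqF = 0, lqR = 0, dLL = 0, dPR = 0;
      int bFirst = 0, bLastOld = 0;  // affected old block span
      std::vector<double> newBll, newBpr;

      if (kind == 0) {  // switch type of block m
        int m = uniformInt(M);
        int oldT = st.ty[m];
        int r = uniformInt(3);
        int newT = (r >= oldT) ? r + 1 : r;
        nty[m] = newT;
        lqF = S.kindLogP(M, hasLong) - std::log((double)M) - std::log(3.0);
        lqR = S.kindLogP(M, hasLong) - std::log((double)M) - std::log(3.0);
        if (!S.valid(nty, nlen)) goto invalid;
        int s = 1;
        for (int b = 0; b < m; ++b) s += st.len[b];
        int e = s + st.len[m] - 1;
        newBll.push_back(S.segLL(newT, s, e));
        newBpr.push_back(S.segPR(newT, s, e));
        dLL = newBll[0] - st.bll[m];
        dPR = newBpr[0] - st.bpr[m];
        bFirst = m; bLastOld = m;
      } else if (kind == 1) {  // move boundary between blocks j, j+1
        int j = uniformInt(M - 1);
        int total = st.len[j] + st.len[j + 1];
        int newLeft = 1 + uniformInt(total - 1);
        nlen[j] = newLeft; nlen[j + 1] = total - newLeft;
        lqF = S.kindLogP(M, hasLong) - std::log((double)(M - 1)) -
              std::log((double)(total - 1));
        lqR = S.kindLogP(M, Sampler::anyLong(nlen)) -
              std::log((double)(M - 1)) - std::log((double)(total - 1));
        if (!S.valid(nty, nlen)) goto invalid;
        int s = 1;
        for (int b = 0; b < j; ++b) s += st.len[b];
        int mid = s + newLeft - 1, e = s + total - 1;
        newBll.push_back(S.segLL(st.ty[j], s, mid));
        newBll.push_back(S.segLL(st.ty[j + 1], mid + 1, e));
        newBpr.push_back(S.segPR(st.ty[j], s, mid));
        newBpr.push_back(S.segPR(st.ty[j + 1], mid + 1, e));
        dLL = newBll[0] + newBll[1] - st.bll[j] - st.bll[j + 1];
        dPR = newBpr[0] + newBpr[1] - st.bpr[j] - st.bpr[j + 1];
        bFirst = j; bLastOld = j + 1;
      } else if (kind == 2) {  // split an eligible block
        int nElig = 0;
        for (int b = 0; b < M; ++b) if (st.len[b] >= 2) ++nElig;
        int r = uniformInt(nElig), j = -1;
        for (int b = 0; b < M; ++b) {
          if (st.len[b] < 2) continue;
          if (r == 0) { j = b; break; }
          --r;
        }
        int lenj = st.len[j];
        int left = 1 + uniformInt(lenj - 1);
        int rightT = uniformInt(4);
        nty.insert(nty.begin() + j + 1, rightT);
        nlen[j] = left;
        nlen.insert(nlen.begin() + j + 1, lenj - left);
        lqF = S.kindLogP(M, hasLong) - std::log((double)nElig) -
              std::log((double)(lenj - 1)) - std::log(4.0);
        // reverse: merge pair j in the (M+1)-block candidate
        lqR = S.kindLogP(M + 1, Sampler::anyLong(nlen)) -
              std::log((double)M);
        if (!S.valid(nty, nlen)) goto invalid;
        int s = 1;
        for (int b = 0; b < j; ++b) s += st.len[b];
        int mid = s + left - 1, e = s + lenj - 1;
        newBll.push_back(S.segLL(st.ty[j], s, mid));
        newBll.push_back(S.segLL(rightT, mid + 1, e));
        newBpr.push_back(S.segPR(st.ty[j], s, mid));
        newBpr.push_back(S.segPR(rightT, mid + 1, e));
        dLL = newBll[0] + newBll[1] - st.bll[j];
        dPR = newBpr[0] + newBpr[1] - st.bpr[j];
        bFirst = j; bLastOld = j;
      } else {  // merge pair j, j+1 into the left block's type
        int j = uniformInt(M - 1);
        int total = st.len[j] + st.len[j + 1];
        nty.erase(nty.begin() + j + 1);
        nlen[j] = total;
        nlen.erase(nlen.begin() + j + 1);
        lqF = S.kindLogP(M, hasLong) - std::log((double)(M - 1));
        int nEligC = 0;
        for (size_t b = 0; b < nlen.size(); ++b) if (nlen[b] >= 2) ++nEligC;
        lqR = S.kindLogP(M - 1, true) - std::log((double)nEligC) -
              std::log((double)(total - 1)) - std::log(4.0);
        if (!S.valid(nty, nlen)) goto invalid;
        int s = 1;
        for (int b = 0; b < j; ++b) s += st.len[b];
        int e = s + total - 1;
        newBll.push_back(S.segLL(st.ty[j], s, e));
        newBpr.push_back(S.segPR(st.ty[j], s, e));
        dLL = newBll[0] - st.bll[j] - st.bll[j + 1];
        dPR = newBpr[0] - st.bpr[j] - st.bpr[j + 1];
        bFirst = j; bLastOld = j + 1;
      }

      ++nValid;
      {
        double logr = dLL + dPR + lqR - lqF;
        if (logr >= 0 || std::log(unif_rand()) < logr) {
          ++nAccept;
          // splice caches: replace old blocks [bFirst..bLastOld] by new
          st.bll.erase(st.bll.begin() + bFirst, st.bll.begin() + bLastOld + 1);
          st.bpr.erase(st.bpr.begin() + bFirst, st.bpr.begin() + bLastOld + 1);
          st.bll.insert(st.bll.begin() + bFirst, newBll.begin(), newBll.end());
          st.bpr.insert(st.bpr.begin() + bFirst, newBpr.begin(), newBpr.end());
          st.ty = nty; st.len = nlen;
          st.curLL += dLL; st.curPR += dPR;
        }
      }
      goto accumulate;
    }

  invalid:
    ;  // candidate violates hard constraints: prior zero, always rejected

  accumulate:
    if (iter > burnin) {
      // current state counts, accepted or not
      int s = 0;
      for (size_t b = 0; b < st.ty.size(); ++b) {
        int t = st.ty[b];
        for (int p = 0; p < st.len[b]; ++p) marg(s + p, t) += 1.0;
        s += st.len[b];
      }
      // canonical block counts
      int cTot = 0, cBy[4] = {0, 0, 0, 0};
      for (size_t b = 0; b < st.ty.size(); ++b) {
        if (b == 0 || st.ty[b] != st.ty[b - 1]) { ++cTot; ++cBy[st.ty[b]]; }
      }
      mTotal[cTot] += 1.0;
      for (int t = 0; t < 4; ++t) mByType[t][cBy[t]] += 1.0;
      double lp = st.curLL + st.curPR;
      if (lp > bestLP) {
        bestLP = lp; bestTy = st.ty; bestLen = st.len; bestIter = iter;
      }
      int post = iter - burnin;
      if (thin > 0 && post % thin == 0) trace.push_back(lp);
      if (trackStates && !freqOverflow) {
        if ((int)freq.size() >= maxStates) freqOverflow = true;
        else freq[stateKey(st.ty, st.len)] += 1.0;
      }
      if (keepEvery > 0 && post % keepEvery == 0) {
        sampTy.push_back(st.ty);
        sampLen.push_back(st.len);
      }
    }
  }

  long nRetained = nProposals - burnin;
  for (int p = 0; p < S.L; ++p)
    for (int t = 0; t < 4; ++t) marg(p, t) /= (double)nRetained;

  // pack block-count maps
  auto packMap = [&](std::map<int, double>& m) {
    IntegerVector k(m.size());
    NumericVector v(m.size());
    int i = 0;
    for (std::map<int, double>::iterator it = m.begin(); it != m.end(); ++it) {
      k[i] = it->first; v[i] = it->second / (double)nRetained; ++i;
    }
    v.attr("names") = as<CharacterVector>(wrap(k));
    return v;
  };
  List byType = List::create(packMap(mByType[0]), packMap(mByType[1]),
                             packMap(mByType[2]), packMap(mByType[3]));
  CharacterVector fk(freq.size());
  NumericVector fv(freq.size());
  {
    int i = 0;
    for (std::map<std::string, double>::iterator it = freq.begin();
         it != freq.end(); ++it) {
      fk[i] = it->first; fv[i] = it->second / (double)nRetained; ++i;
    }
    fv.attr("names") = fk;
  }
  List sampOut(sampTy.size());
  for (size_t i = 0; i < sampTy.size(); ++i)
    sampOut[i] = List::create(_["ty"] = wrap(sampTy[i]),
                              _["len"] = wrap(sampLen[i]));

  return List::create(
      _["marginals"] = marg,
      _["bestTy"] = wrap(bestTy), _["bestLen"] = wrap(bestLen),
      _["bestLogPost"] = bestLP, _["bestIter"] = (double)bestIter,
      _["trace"] = wrap(trace),
      _["blockTotal"] = packMap(mTotal), _["blockByType"] = byType,
      _["stateFreq"] = fv, _["stateFreqOverflow"] = freqOverflow,
      _["nAccept"] = (double)nAccept, _["nValid"] = (double)nValid,
      _["nResampled"] = (double)nResampled,
      _["nInfeasibleRejected"] = (double)nInfeasibleRejected,
      _["nRetained"] = (double)nRetained,
      _["finalTy"] = wrap(st.ty), _["finalLen"] = wrap(st.len),
      _["finalLogPost"] = st.curLL + st.curPR,
      _["samples"] = sampOut);
}
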