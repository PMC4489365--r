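// (6,6) body-bar pebble game engine and macrostate Monte Carlo sampler.
//
// Atoms are rigid bodies carrying 6 pebbles (degrees of freedom); every bar
// between two bodies is independent iff 7 pebbles can be gathered on its two
// endpoints, in which case it consumes one pebble.  Bars are inserted in
// preferential order (ascending component entropy) so that the conformational
// entropy computed from the independent set is the lowest upper bound.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <vector>
#include <array>
#include <map>
#include <algorithm>
#include <numeric>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ------------------------------------------------------------------
// pebble graph
// ------------------------------------------------------------------

struct PebbleGraph {
  int V = 0;
  int nPairs = 0;
  std::vector<int> lo;                 // lower vertex of each pair slot
  std::vector<int> peb;                // free pebbles per vertex
  std::vector<int> cnt;                // consumed directed counts: 2 per slot
  std::vector<std::vector<std::pair<int,int>>> adj;  // (neighbour, outIdx)
  // DFS scratch
  std::vector<int> vis, parV, parE, stk;
  int stamp = 0;

  void init(int V_, const std::vector<std::pair<int,int>>& pairs) {
    V = V_; nPairs = (int) pairs.size();
    lo.resize(nPairs);
    peb.assign(V, 6);
    cnt.assign(2 * (size_t) nPairs, 0);
    adj.assign(V, {});
    for (int s = 0; s < nPairs; ++s) {
      int a = pairs[s].first, b = pairs[s].second;
      lo[s] = std::min(a, b);
      adj[a].push_back({b, (a == lo[s]) ? 2 * s : 2 * s + 1});
      adj[b].push_back({a, (b == lo[s]) ? 2 * s : 2 * s + 1});
    }
    vis.assign(V, 0); parV.assign(V, -1); parE.assign(V, -1);
    stamp = 0;
  }

  int dirIdx(int from, int slot) const {
    return (from == lo[slot]) ? 2 * slot : 2 * slot + 1;
  }

  // move one free pebble onto {u, v}; on failure optionally record the
  // visited (reach) set, which is the over-constrained vertex set.
  bool findPebble(int u, int v, std::vector<int>* failset) {
    ++stamp;
    stk.clear();
    vis[u] = stamp; vis[v] = stamp;
    parV[u] = -1; parV[v] = -1;
    stk.push_back(u); stk.push_back(v);
    size_t head = 0;
    while (head < stk.size()) {
      int x = stk[head++];
      for (const auto& e : adj[x]) {
        if (cnt[e.second] > 0) {
          int w = e.first;
          if (vis[w] != stamp) {
            vis[w] = stamp; parV[w] = x; parE[w] = e.second;
            if (peb[w] > 0) {
              // reverse the search path, carrying the pebble back
              int c = w;
              while (parV[c] != -1) {
                int pe = parE[c];
                cnt[pe]--; cnt[pe ^ 1]++;
                c = parV[c];
              }
              peb[w]--; peb[c]++;
              return true;
            }
            stk.push_back(w);
          }
        }
      }
    }
    if (failset) failset->assign(stk.begin(), stk.end());
    return false;
  }

  bool gather7(int u, int v, std::vector<int>* failset = nullptr) {
    while (peb[u] + peb[v] < 7) {
      if (!findPebble(u, v, failset)) return false;
    }
    return true;
  }

  // insert one bar on pair slot; true iff independent
  bool insert(int u, int v, int slot, std::vector<int>* failset = nullptr) {
    if (!gather7(u, v, failset)) return false;
    if (peb[u] > 0) { peb[u]--; cnt[dirIdx(u, slot)]++; }
    else           { peb[v]--; cnt[dirIdx(v, slot)]++; }
    return true;
  }

  // mutually rigid iff a 7th pebble cannot be gathered on the pair.
  // On a rigid pair the failed reach set holds exactly 6 free pebbles, so
  // it spans 6|R|-6 independent bars: the whole set is one rigid body.
  bool pairRigid(int u, int v, std::vector<int>* failset = nullptr) {
    return !gather7(u, v, failset);
  }
};

// deterministic union-find (lowest index becomes the root)
struct UF {
  std::vector<int> p;
  void init(int n) { p.resize(n); std::iota(p.begin(), p.end(), 0); }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (a < b) p[b] = a; else p[a] = b;
  }
};

// ------------------------------------------------------------------
// generic pebble game over an explicit bar list (oracle / property tests)
// ------------------------------------------------------------------

// [[Rcpp::export]]
List pg_run_cpp(int V, IntegerVector ui, IntegerVector vi) {
  int n = ui.size();
  std::map<std::pair<int,int>, int> slotOf;
  std::vector<std::pair<int,int>> pairs;
  std::vector<int> slot(n), uu(n), vv(n);
  for (int i = 0; i < n; ++i) {
    int a = ui[i] - 1, b = vi[i] - 1;
    if (a < 0 || b < 0 || a >= V || b >= V) stop("bar endpoint out of range");
    if (a == b) stop("self-loop bar not allowed in a body-bar framework");
    std::pair<int,int> key = {std::min(a, b), std::max(a, b)};
    auto it = slotOf.find(key);
    if (it == slotOf.end()) {
      slotOf[key] = (int) pairs.size();
      slot[i] = (int) pairs.size();
      pairs.push_back(key);
    } else slot[i] = it->second;
    uu[i] = a; vv[i] = b;
  }
  PebbleGraph pg;
  pg.init(V, pairs);
  LogicalVector ind(n);
  for (int i = 0; i < n; ++i) ind[i] = pg.insert(uu[i], vv[i], slot[i]);
  return List::create(_["independent"] = ind,
                      _["free_pebbles"] = IntegerVector(pg.peb.begin(), pg.peb.end()));
}

// ------------------------------------------------------------------
// molecular engine: covalent base + torsion sites + H-bond inventory
// ------------------------------------------------------------------

struct MolEngine {
  int V = 0, S = 0, H = 0;
  // expanded covalent bars: u, v, slot
  std::vector<std::array<int,3>> covBar;
  // bond-level covalent pairs: u, v, rotatable, slot
  std::vector<std::array<int,4>> covPair;
  // sites: a, u, v, d (outer a-d carry the torsion bar), slot of (a,d)
  std::vector<std::array<int,5>> site;
  // H-bonds: h, acc, slot
  std::vector<std::array<int,3>> hb;
  std::vector<double> gamma, energy;
  double dnat = 0, ddis = 0;

  PebbleGraph pg;

  // entropy-run order: (type, id); type 0 = site@delta_nat, 1 = site@delta_dis,
  // 2 = H-bond block.  mech order: natives + H-bonds only.
  std::vector<std::pair<int,int>> entOrder, mechOrder;

  // covalent-phase snapshot
  std::vector<int> peb0, cnt0, ufc0, ufs0;
  std::vector<char> instress0;
  std::vector<int> failRep0;
  std::vector<char> covIndep;

  void build(int V_, const IntegerMatrix& covBars, const IntegerMatrix& covPairs,
             const IntegerMatrix& sites, const IntegerMatrix& hbm,
             const NumericVector& hbGamma, const NumericVector& hbEnergy,
             double deltaNat, double deltaDis) {
    V = V_; S = sites.nrow(); H = hbm.nrow();
    dnat = deltaNat; ddis = deltaDis;
    std::map<std::pair<int,int>, int> slotOf;
    std::vector<std::pair<int,int>> pairs;
    auto getSlot = [&](int a, int b) {
      std::pair<int,int> key = {std::min(a, b), std::max(a, b)};
      auto it = slotOf.find(key);
      if (it != slotOf.end()) return it->second;
      int s = (int) pairs.size();
      slotOf[key] = s; pairs.push_back(key);
      return s;
    };
    covBar.resize(covBars.nrow());
    for (int i = 0; i < covBars.nrow(); ++i) {
      int a = covBars(i,0) - 1, b = covBars(i,1) - 1;
      covBar[i] = {a, b, getSlot(a, b)};
    }
    covPair.resize(covPairs.nrow());
    for (int i = 0; i < covPairs.nrow(); ++i) {
      int a = covPairs(i,0) - 1, b = covPairs(i,1) - 1;
      covPair[i] = {a, b, covPairs(i,2), getSlot(a, b)};
    }
    site.resize(S);
    for (int i = 0; i < S; ++i) {
      int a = sites(i,0) - 1, u = sites(i,1) - 1, v = sites(i,2) - 1, d = sites(i,3) - 1;
      site[i] = {a, u, v, d, getSlot(a, d)};
    }
    hb.resize(H);
    gamma.assign(hbGamma.begin(), hbGamma.end());
    energy.assign(hbEnergy.begin(), hbEnergy.end());
    for (int i = 0; i < H; ++i) {
      int h = hbm(i,0) - 1, acc = hbm(i,1) - 1;
      hb[i] = {h, acc, getSlot(h, acc)};
    }
    pg.init(V, pairs);

    // preferential orders: ascending component entropy; ties resolved by
    // inventory position (torsion sites before H-bonds, then index)
    std::vector<std::pair<int,int>> ent;
    for (int s = 0; s < S; ++s) ent.push_back({0, s});
    for (int s = 0; s < S; ++s) ent.push_back({1, s});
    for (int t = 0; t < H; ++t) ent.push_back({2, t});
    auto entVal = [&](const std::pair<int,int>& e) {
      if (e.first == 0) return dnat;
      if (e.first == 1) return ddis;
      return gamma[e.second];
    };
    std::stable_sort(ent.begin(), ent.end(),
                     [&](const std::pair<int,int>& x, const std::pair<int,int>& y) {
                       return entVal(x) < entVal(y);
                     });
    entOrder = ent;
    std::vector<std::pair<int,int>> mech;
    for (int s = 0; s < S; ++s) mech.push_back({0, s});
    for (int t = 0; t < H; ++t) mech.push_back({2, t});
    std::stable_sort(mech.begin(), mech.end(),
                     [&](const std::pair<int,int>& x, const std::pair<int,int>& y) {
                       return entVal(x) < entVal(y);
                     });
    mechOrder = mech;

    // covalent phase (shared by every sampled topology)
    UF ufc; ufc.init(V);
    UF ufs; ufs.init(V);
    instress0.assign(V, 0);
    covIndep.assign(covBar.size(), 0);
    std::vector<int> failset;
    for (size_t i = 0; i < covBar.size(); ++i) {
      failset.clear();
      if (pg.insert(covBar[i][0], covBar[i][1], covBar[i][2], &failset)) {
        covIndep[i] = 1;
      } else {
        for (size_t k = 1; k < failset.size(); ++k) ufs.unite(failset[0], failset[k]);
        for (int x : failset) instress0[x] = 1;
        failRep0.push_back(failset[0]);
      }
    }
    // non-rotatable covalent bonds always join their endpoints rigidly
    for (const auto& b : covPair) if (!b[2]) ufc.unite(b[0], b[1]);
    peb0 = pg.peb; cnt0 = pg.cnt; ufc0 = ufc.p; ufs0 = ufs.p;
  }

  void restore() { pg.peb = peb0; pg.cnt = cnt0; }

  // ---- entropy run (strict preferential order over the full bar set) ----
  // native / pres are masks; outputs per Eq 2.
  void entropyRun(const std::vector<char>& native, const std::vector<char>& pres,
                  double& qgammaSum, int& Qnat, int& Qdis,
                  std::vector<int>* qPerHb = nullptr,
                  std::vector<char>* siteIndep = nullptr) {
    restore();
    qgammaSum = 0; Qnat = 0; Qdis = 0;
    if (qPerHb) qPerHb->assign(H, 0);
    if (siteIndep) siteIndep->assign(S, 0);
    for (const auto& e : entOrder) {
      if (e.first == 0) {
        int s = e.second;
        if (!native[s]) continue;
        if (pg.insert(site[s][0], site[s][3], site[s][4])) {
          Qnat++; if (siteIndep) (*siteIndep)[s] = 1;
        }
      } else if (e.first == 1) {
        int s = e.second;
        if (native[s]) continue;
        if (pg.insert(site[s][0], site[s][3], site[s][4])) {
          Qdis++; if (siteIndep) (*siteIndep)[s] = 1;
        }
      } else {
        int t = e.second;
        if (!pres[t]) continue;
        int q = 0;
        for (int b = 0; b < 5; ++b)
          if (pg.insert(hb[t][0], hb[t][1], hb[t][2])) q++;
        qgammaSum += q * gamma[t];
        if (qPerHb) (*qPerHb)[t] = q;
      }
    }
  }

  // ---- mechanical run -------------------------------------------------
  // Network of covalent + native torsion + H-bond bars; disordered torsion
  // bars are probes inserted last.  Produces locked flags, flexible /
  // over-constrained region membership and per-site flexibility f.
  struct MechOut {
    std::vector<char> locked;      // per site
    std::vector<double> f;         // per site
    std::vector<int> flexreg;      // per site, -1 if locked
    std::vector<int> stressreg;    // per site, -1 if not in a stressed region
    std::vector<char> probeIndep;  // per site (disordered probe independent)
    std::vector<int> cluster;      // per atom (root vertex of rigid cluster)
    std::vector<int> Hcount, Acount;  // indexed by flexible-region root
    std::vector<int> Lcount, Bcount;  // indexed by stress-region root
    // entropy counts collected during the mechanical run (valid as the
    // strict preferential order whenever every present gamma < delta_dis)
    double qgamma = 0; int Qnat = 0, Qdis = 0;
    std::vector<int> qPerHb;
    void init(int V, int S, int H) {
      locked.assign(S, 0); f.assign(S, 0.0);
      flexreg.assign(S, -1); stressreg.assign(S, -1);
      probeIndep.assign(S, 0); cluster.assign(V, 0);
      Hcount.assign(V, 0); Acount.assign(V, 0);
      Lcount.assign(V, 0); Bcount.assign(V, 0);
      qPerHb.assign(H, 0);
      qgamma = 0; Qnat = 0; Qdis = 0;
    }
  };

  // scratch reused across samples
  std::vector<int> failset_, failRep_;
  std::vector<char> instress_;
  UF ufs_, ufc_, uff_;

  void mechRun(const std::vector<char>& native, const std::vector<char>& pres,
               MechOut& out) {
    restore();
    out.init(V, S, H);
    ufs_.p = ufs0;
    instress_ = instress0;
    failRep_ = failRep0;
    auto recordFail = [&]() {
      for (size_t k = 1; k < failset_.size(); ++k) ufs_.unite(failset_[0], failset_[k]);
      for (int x : failset_) instress_[x] = 1;
      failRep_.push_back(failset_[0]);
    };
    for (const auto& e : mechOrder) {
      if (e.first == 0) {
        int s = e.second;
        if (!native[s]) continue;
        failset_.clear();
        if (pg.insert(site[s][0], site[s][3], site[s][4], &failset_)) out.Qnat++;
        else recordFail();
      } else {
        int t = e.second;
        if (!pres[t]) continue;
        int q = 0;
        for (int b = 0; b < 5; ++b) {
          failset_.clear();
          if (pg.insert(hb[t][0], hb[t][1], hb[t][2], &failset_)) q++;
          else recordFail();
        }
        out.qPerHb[t] = q;
        out.qgamma += q * gamma[t];
      }
    }

    // rigid clusters + locked bonds.  Mutual rigidity of bodies is an
    // equivalence, so adjacent-pair tests plus union-find closure suffice.
    ufc_.p = ufc0;
    auto rigidPairTest = [&](int u, int v) {
      if (ufc_.find(u) == ufc_.find(v)) return true;
      failset_.clear();
      if (pg.pairRigid(u, v, &failset_)) {
        // the whole blocked reach set is one rigid body
        for (size_t k = 1; k < failset_.size(); ++k)
          ufc_.unite(failset_[0], failset_[k]);
        return true;
      }
      return false;
    };
    for (int s = 0; s < S; ++s)
      if (rigidPairTest(site[s][1], site[s][2])) out.locked[s] = 1;
    // rotatable covalent bonds that carry no torsion site (e.g. bonds whose
    // outer neighbours are hydrogens) still join clusters when rigid
    for (const auto& b : covPair)
      if (b[2]) rigidPairTest(b[0], b[1]);
    for (int t = 0; t < H; ++t)
      if (pres[t]) rigidPairTest(hb[t][0], hb[t][1]);
    for (int x = 0; x < V; ++x) out.cluster[x] = ufc_.find(x);

    // flexible regions: contract rigid clusters, connect through unlocked sites
    uff_.p = ufc_.p;
    for (int s = 0; s < S; ++s)
      if (!out.locked[s]) uff_.unite(site[s][1], site[s][2]);
    for (int s = 0; s < S; ++s) {
      if (!out.locked[s]) {
        int r = uff_.find(site[s][1]);
        out.flexreg[s] = r;
        out.Hcount[r]++;
      }
    }

    // over-constrained regions
    for (int rep : failRep_) out.Bcount[ufs_.find(rep)]++;
    for (int s = 0; s < S; ++s) {
      if (!out.locked[s]) continue;
      int u = site[s][1], v = site[s][2];
      if (instress_[u] && instress_[v] && ufs_.find(u) == ufs_.find(v)) {
        int r = ufs_.find(u);
        if (out.Bcount[r] > 0) { out.stressreg[s] = r; out.Lcount[r]++; }
      }
    }

    // disordered probes: independent probes count the region's internal DOF
    for (int s = 0; s < S; ++s) {
      if (native[s] || out.locked[s]) continue;
      if (pg.insert(site[s][0], site[s][3], site[s][4])) {
        out.probeIndep[s] = 1;
        out.Qdis++;
        out.Acount[out.flexreg[s]]++;
      }
    }

    // flexibility index per site
    for (int s = 0; s < S; ++s) {
      if (!out.locked[s]) {
        int r = out.flexreg[s];
        out.f[s] = (double) out.Acount[r] / (double) out.Hcount[r];
      } else if (out.stressreg[s] >= 0) {
        int r = out.stressreg[s];
        out.f[s] = -((double) out.Bcount[r] / (double) out.Lcount[r]);
      }
    }
  }
};

static MolEngine buildEngine(int V, const IntegerMatrix& covBars,
                             const IntegerMatrix& covPairs,
                             const IntegerMatrix& sites, const IntegerMatrix& hbm,
                             const NumericVector& hbGamma, const NumericVector& hbEnergy,
                             double deltaNat, double deltaDis) {
  MolEngine eng;
  eng.build(V, covBars, covPairs, sites, hbm, hbGamma, hbEnergy, deltaNat, deltaDis);
  return eng;
}

// ------------------------------------------------------------------
// single-framework report (decomposition + entropy counts)
// ------------------------------------------------------------------

// [[Rcpp::export]]
List framework_report_cpp(int V, IntegerMatrix covBars, IntegerMatrix covPairs,
                          IntegerMatrix sites, IntegerMatrix hbm,
                          NumericVector hbGamma, NumericVector hbEnergy,
                          LogicalVector nativeMask, LogicalVector hbPresent,
                          double deltaNat, double deltaDis) {
  MolEngine eng = buildEngine(V, covBars, covPairs, sites, hbm, hbGamma, hbEnergy,
                              deltaNat, deltaDis);
  std::vector<char> native(nativeMask.begin(), nativeMask.end());
  std::vector<char> pres(hbPresent.begin(), hbPresent.end());

  double qg; int Qn, Qd;
  std::vector<int> qPerHb;
  std::vector<char> siteIndep;
  eng.entropyRun(native, pres, qg, Qn, Qd, &qPerHb, &siteIndep);

  MolEngine::MechOut mo;
  eng.mechRun(native, pres, mo);

  int S = eng.S;
  NumericVector f(S);
  IntegerVector flexreg(S), stressreg(S), lockedv(S), probe(S), sindep(S);
  IntegerVector Hs(S), As(S), Ls(S), Bs(S);
  for (int s = 0; s < S; ++s) {
    f[s] = mo.f[s];
    lockedv[s] = mo.locked[s];
    probe[s] = mo.probeIndep[s];
    sindep[s] = siteIndep[s];
    flexreg[s] = (mo.flexreg[s] >= 0) ? mo.flexreg[s] + 1 : NA_INTEGER;
    stressreg[s] = (mo.stressreg[s] >= 0) ? mo.stressreg[s] + 1 : NA_INTEGER;
    Hs[s] = (mo.flexreg[s] >= 0) ? mo.Hcount[mo.flexreg[s]] : NA_INTEGER;
    As[s] = (mo.flexreg[s] >= 0) ? mo.Acount[mo.flexreg[s]] : NA_INTEGER;
    Ls[s] = (mo.stressreg[s] >= 0) ? mo.Lcount[mo.stressreg[s]] : NA_INTEGER;
    Bs[s] = (mo.stressreg[s] >= 0) ? mo.Bcount[mo.stressreg[s]] : NA_INTEGER;
  }
  IntegerVector clu(V);
  for (int x = 0; x < V; ++x) clu[x] = mo.cluster[x] + 1;
  return List::create(
    _["cov_independent"] = LogicalVector(eng.covIndep.begin(), eng.covIndep.end()),
    _["q_per_hbond"] = IntegerVector(qPerHb.begin(), qPerHb.end()),
    _["Q_nat"] = Qn, _["Q_dis"] = Qd, _["qgamma"] = qg,
    _["site_bar_independent"] = sindep,
    _["locked"] = lockedv, _["f"] = f,
    _["flex_region"] = flexreg, _["stress_region"] = stressreg,
    _["region_H"] = Hs, _["region_A"] = As,
    _["region_L"] = Ls, _["region_B"] = Bs,
    _["probe_independent"] = probe,
    _["atom_cluster"] = clu);
}

// ------------------------------------------------------------------
// macrostate grid Monte Carlo sampler
// ------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline int randBelow(uint64_t& st, int n) {
  return (int) (splitmix64(st) % (uint64_t) n);
}

// [[Rcpp::export]]
List dcm_sample_grid_cpp(int V, IntegerMatrix covBars, IntegerMatrix covPairs,
                         IntegerMatrix sites, IntegerMatrix hbm,
                         NumericVector hbGamma, NumericVector hbEnergy,
                         double deltaNat, double deltaDis,
                         IntegerVector nodeNhb, IntegerVector nodeNnat,
                         int nSamples, double seed,
                         IntegerVector ccSites) {
  MolEngine eng = buildEngine(V, covBars, covPairs, sites, hbm, hbGamma, hbEnergy,
                              deltaNat, deltaDis);
  int S = eng.S, H = eng.H;
  int nNodes = nodeNhb.size();
  int nCC = ccSites.size();
  std::vector<int> ccIdx(ccSites.begin(), ccSites.end());  // 1-based from R
  for (int& x : ccIdx) x -= 1;

  NumericVector Umean(nNodes), Uvar(nNodes);
  NumericVector qgMean(nNodes), QnatMean(nNodes), QdisMean(nNodes);
  NumericVector SconfMean(nNodes), SconfVar(nNodes);
  NumericMatrix fMean(nNodes, S), fVar(nNodes, S), lockedFreq(nNodes, S);
  NumericMatrix ccMean(nCC > 0 ? nCC * nCC : 1, nCC > 0 ? nNodes : 1);

  std::vector<int> hbIdx(H), siteIdx(S);
  std::vector<char> native(S), pres(H);
  std::vector<double> fsum(S), fsq(S), lsum(S);
  std::vector<double> ccsum((size_t) nCC * nCC);
  MolEngine::MechOut mo;

  for (int nd = 0; nd < nNodes; ++nd) {
    int Nhb = nodeNhb[nd], Nnat = nodeNnat[nd];
    if (Nhb < 0 || Nhb > H || Nnat < 0 || Nnat > S)
      stop("macrostate outside the (N_hb, N_nat) inventory");
    // per-macrostate RNG stream: hash of (seed, N_hb, N_nat)
    uint64_t st = (uint64_t) seed;
    splitmix64(st);
    st ^= 0x9E3779B97F4A7C15ULL * (uint64_t) (Nhb + 1);
    splitmix64(st);
    st ^= 0xC2B2AE3D27D4EB4FULL * (uint64_t) (Nnat + 1);
    splitmix64(st);

    double sU = 0, sU2 = 0, sQg = 0, sQn = 0, sQd = 0, sS = 0, sS2 = 0;
    std::fill(fsum.begin(), fsum.end(), 0.0);
    std::fill(fsq.begin(), fsq.end(), 0.0);
    std::fill(lsum.begin(), lsum.end(), 0.0);
    std::fill(ccsum.begin(), ccsum.end(), 0.0);

    for (int it = 0; it < nSamples; ++it) {
      // uniform random subsets (partial Fisher-Yates)
      std::iota(hbIdx.begin(), hbIdx.end(), 0);
      std::iota(siteIdx.begin(), siteIdx.end(), 0);
      std::fill(pres.begin(), pres.end(), 0);
      std::fill(native.begin(), native.end(), 0);
      double U = 0, maxGamma = -1;
      for (int k = 0; k < Nhb; ++k) {
        int j = k + randBelow(st, H - k);
        std::swap(hbIdx[k], hbIdx[j]);
        pres[hbIdx[k]] = 1;
        U += eng.energy[hbIdx[k]];
        maxGamma = std::max(maxGamma, eng.gamma[hbIdx[k]]);
      }
      for (int k = 0; k < Nnat; ++k) {
        int j = k + randBelow(st, S - k);
        std::swap(siteIdx[k], siteIdx[j]);
        native[siteIdx[k]] = 1;
      }

      eng.mechRun(native, pres, mo);
      double qg; int Qn, Qd;
      if (maxGamma < deltaDis) {
        // the strict entropy-ascending order coincides with the mechanical
        // run followed by the disordered probes: reuse its counts
        qg = mo.qgamma; Qn = mo.Qnat; Qd = mo.Qdis;
      } else {
        eng.entropyRun(native, pres, qg, Qn, Qd);
      }
      double sconf = qg + Qn * deltaNat + Qd * deltaDis;
      sU += U; sU2 += U * U;
      sQg += qg; sQn += Qn; sQd += Qd;
      sS += sconf; sS2 += sconf * sconf;
      for (int s = 0; s < S; ++s) {
        fsum[s] += mo.f[s]; fsq[s] += mo.f[s] * mo.f[s];
        lsum[s] += mo.locked[s];
      }
      if (nCC > 0) {
        for (int i = 0; i < nCC; ++i) {
          int si = ccIdx[i];
          ccsum[(size_t) i * nCC + i] += mo.f[si];
          for (int j = i + 1; j < nCC; ++j) {
            int sj = ccIdx[j];
            bool same =
              (mo.flexreg[si] >= 0 && mo.flexreg[si] == mo.flexreg[sj]) ||
              (mo.stressreg[si] >= 0 && mo.stressreg[si] == mo.stressreg[sj]);
            if (same) {
              double vcc = mo.f[si];
              ccsum[(size_t) i * nCC + j] += vcc;
              ccsum[(size_t) j * nCC + i] += vcc;
            }
          }
        }
      }
    }
    double n = (double) nSamples;
    Umean[nd] = sU / n;
    Uvar[nd] = (n > 1) ? std::max(0.0, (sU2 - n * (sU / n) * (sU / n)) / (n - 1)) : 0.0;
    qgMean[nd] = sQg / n; QnatMean[nd] = sQn / n; QdisMean[nd] = sQd / n;
    SconfMean[nd] = sS / n;
    SconfVar[nd] = (n > 1) ? std::max(0.0, (sS2 - n * (sS / n) * (sS / n)) / (n - 1)) : 0.0;
    for (int s = 0; s < S; ++s) {
      double m = fsum[s] / n;
      fMean(nd, s) = m;
      fVar(nd, s) = (n > 1) ? std::max(0.0, (fsq[s] - n * m * m) / (n - 1)) : 0.0;
      lockedFreq(nd, s) = lsum[s] / n;
    }
    if (nCC > 0)
      for (size_t k = 0; k < ccsum.size(); ++k) ccMean(k, nd) = ccsum[k] / n;
  }

  return List::create(
    _["U_mean"] = Umean, _["U_var"] = Uvar,
    _["qgamma_mean"] = qgMean, _["Qnat_mean"] = QnatMean, _["Qdis_mean"] = QdisMean,
    _["Sconf_mean"] = SconfMean, _["Sconf_var"] = SconfVar,
    _["f_mean"] = fMean, _["f_var"] = fVar, _["locked_freq"] = lockedFreq,
    _["cc_mean"] = ccMean);
}

// ------------------------------------------------------------------
// pairwise RMSD matrix (Kabsch, closed-form via 3x3 SVD)
// ------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix rmsd_matrix_cpp(NumericVector coords, IntegerVector sel) {
  IntegerVector dim = coords.attr("dim");
  if (dim.size() != 3 || dim[1] != 3) stop("coords must be an (atoms x 3 x frames) array");
  int na = dim[0], nf = dim[2], ns = sel.size();
  if (ns < 1) stop("empty selection");
  std::vector<arma::mat> X(nf);
  std::vector<double> tr(nf);
  const double* cp = coords.begin();
  for (int f = 0; f < nf; ++f) {
    arma::mat M(ns, 3);
    for (int k = 0; k < 3; ++k) {
      for (int i = 0; i < ns; ++i) {
        int a = sel[i] - 1;
        M(i, k) = cp[a + (size_t) na * k + (size_t) 3 * na * f];
      }
    }
    arma::rowvec c = arma::mean(M, 0);
    M.each_row() -= c;
    X[f] = M;
    tr[f] = arma::accu(M % M);
  }
  NumericMatrix out(nf, nf);
  arma::vec s;
  arma::mat Uu, Vv;
  for (int i = 0; i < nf; ++i) {
    for (int j = i + 1; j < nf; ++j) {
      arma::mat C = X[i].t() * X[j];
      arma::svd(Uu, s, Vv, C);
      double d = (arma::det(C) < 0) ? -1.0 : 1.0;
      double msd = (tr[i] + tr[j] - 2.0 * (s(0) + s(1) + d * s(2))) / ns;
      if (msd < 0) msd = 0;
      out(i, j) = out(j, i) = std::sqrt(msd);
    }
  }
  return out;
}
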