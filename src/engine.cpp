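// Multiscale kinetic Monte Carlo engine for lignin fractionation.
//
// State layout: explicit chains (S/G unit sequence + per-bond dyad codes),
// a chip/liquor registry with incrementally maintained aggregates, and a
// Gillespie direct-method micro engine coupled to explicit-Euler macro
// balances.  Condensation propensities are aggregated over (nS, nG)
// composition classes (the activation energy depends only on the combined
// molar mass, so all chains of one composition are kinetically identical),
// which keeps the per-step cost independent of the pair count.  All random
// draws go through R's RNG, so set.seed() makes every run reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const int DY_GG = 0, DY_GS = 1, DY_SG = 2, DY_SS = 3;

struct Params {
  // monomer masses (g/mol)
  double mwS = 227.2, mwG = 179.2;
  // Arrhenius constants (min^-1, kJ/mol); R in J/mol/K
  double A_dep = 4.8e22, A_con = 2.5e20, A_dem = 9.5e104;
  double E_dem = 764.0, Rgas = 8.314;
  // depolymerization energy table: temps (K, sorted) x 4 dyads (kJ/mol)
  std::vector<double> tabT;
  std::vector<std::array<double, 4> > tabE; // tabE[t][dyad]
  // condensation energy function (kJ/mol vs combined g/mol)
  double vertex_mw = 972.0, e_min = 218.0, slope_lo = 0.028947, slope_hi = 0.028947;
  // concentration per chain copy = 1/omega
  double omega = 2e-4;
  // threshold filter
  double ratio_cutoff = 1000.0;
  int max_cond_units = 9; // class-eligibility cap when filtering
  // macro dynamics
  double A_D = 2.2e13, E_D = 97.6, A_R = 3.4e9, E_R = 80.0;
  double M_c = 50.0, M_f = 500.0, CPc = 1.8e-3, CPf = 3.0e-3, CPext = 4.2e-3;
  double U = 0.5, dHR = -0.02, dt = 5e-4, Lc0 = 12.5;
  double temp_tol = 0.005; // K; kinetics cache refresh tolerance
};

struct Chain {
  int id = 0;
  std::vector<uint8_t> units;  // 1 = S, 0 = G
  std::vector<uint8_t> dyads;  // bond contexts, length = units-1
  int m[4] = {0, 0, 0, 0};     // bond counts per dyad
  double mw = 0.0;
  int sCount = 0;
  int phase = 0;               // 0 chip, 1 liquor
  bool alive = false;
  // registry positions (liquor structures only valid when phase == 1)
  int posPhase = -1;
  int minDyad = -1, posMin = -1;
  int cls = -1, posCls = -1;

  int nUnits() const { return (int)units.size(); }
  int nBonds() const { return (int)dyads.size(); }
  double fS() const { return units.empty() ? 0.0 : (double)sCount / (double)units.size(); }
};

struct Agg {
  double n = 0, sumMW = 0, sumMW2 = 0, units = 0, sCount = 0;
};

struct Sim {
  Params P;
  bool filtered = true;

  std::vector<Chain> chains;
  std::unordered_map<int, int> id2idx;
  int nextId = 1;

  Agg agg[2];
  double sumFs = 0.0;

  std::vector<int> phaseList[2];
  // liquor depolymerization bookkeeping
  std::vector<int> byMin[4];
  double G[4][4]; // G[minDyad][dyad] = total bond count (kept exact via += ints)
  int capBonds = 1;
  // condensation composition classes
  std::unordered_map<int, int> clsIndex; // key nS*4096+nG
  std::vector<int> clsS, clsG;
  std::vector<double> clsMW;
  std::vector<std::vector<int> > clsMembers;
  std::vector<int> nonempty, posNE;

  // kinetics cache (valid at Tcache)
  double Tcache = -1.0;
  double Ecur[4], kdep[4], kdem_c = 0.0, dEth = 0.0, mwLo = 0.0, mwHi = 0.0;
  bool retain[4][4];
  int rank[4];
  double rcon = 0.0;     // incrementally maintained condensation total
  double retPairs = 0.0; // retained pair count (same maintenance)

  // macro state
  double Lc = 0, Ld = 0, Tc = 353.0, Tf = 353.0, clock = 0.0;
  double accDis = 0.0, accRed = 0.0, massScale = 1.0;

  // counters
  double evDep = 0, evCon = 0, evDem = 0, nTransD = 0, nTransR = 0;
  double candDep = 0, candCon = 0, candDem = 0;
  double retDep = 0, retConC = 0, stepCount = 0, underflow = 0;

  // optional event log
  bool logOn = false;
  std::vector<int> logKind, logA, logB;
  std::vector<double> logT, logDt;

  double conc() const { return 1.0 / P.omega; }

  double arrh(double A, double E, double T) const {
    double k = A * std::exp(-E * 1000.0 / (P.Rgas * T));
    return k;
  }

  double edepAt(int dyad, double T) const {
    const std::vector<double>& ts = P.tabT;
    size_t n = ts.size();
    if (T <= ts.front()) return P.tabE.front()[dyad];
    if (T >= ts.back()) return P.tabE.back()[dyad];
    size_t hi = 1;
    while (ts[hi] < T) ++hi;
    double w = (T - ts[hi - 1]) / (ts[hi] - ts[hi - 1]);
    return (1.0 - w) * P.tabE[hi - 1][dyad] + w * P.tabE[hi][dyad];
  }

  double econ(double mw) const {
    if (mw >= P.vertex_mw) return P.e_min + P.slope_hi * (mw - P.vertex_mw);
    return P.e_min + P.slope_lo * (P.vertex_mw - mw);
  }

  double kcon(double mw) const { return arrh(P.A_con, econ(mw), Tcache); }

  // ---- class helpers -------------------------------------------------
  bool classEligible(const Chain& c) const {
    return !filtered || c.nUnits() <= P.max_cond_units;
  }

  int classOf(int nS, int nG) {
    int key = nS * 4096 + nG;
    auto it = clsIndex.find(key);
    if (it != clsIndex.end()) return it->second;
    int id = (int)clsS.size();
    clsIndex[key] = id;
    clsS.push_back(nS);
    clsG.push_back(nG);
    clsMW.push_back(nS * P.mwS + nG * P.mwG);
    clsMembers.push_back(std::vector<int>());
    posNE.push_back(-1);
    return id;
  }

  bool pairRetained(double mwSum) const {
    return !filtered || (mwSum >= mwLo && mwSum <= mwHi);
  }

  // condensation propensity of one chain against current liquor classes
  void conDelta(const Chain& c, double sign) {
    double C2 = conc() * conc();
    for (size_t k = 0; k < nonempty.size(); ++k) {
      int b = nonempty[k];
      double nb = (double)clsMembers[b].size();
      if (nb <= 0) continue;
      double mwSum = c.mw + clsMW[b];
      if (!pairRetained(mwSum)) continue;
      rcon += sign * C2 * kcon(mwSum) * nb;
      retPairs += sign * nb;
    }
  }

  void classAttach(int idx) {
    Chain& c = chains[idx];
    if (!classEligible(c)) { c.cls = -1; return; }
    conDelta(c, +1.0); // pairs against members present before insertion
    int cl = classOf(c.sCount, c.nUnits() - c.sCount);
    if (clsMembers[cl].empty()) {
      posNE[cl] = (int)nonempty.size();
      nonempty.push_back(cl);
    }
    c.cls = cl;
    c.posCls = (int)clsMembers[cl].size();
    clsMembers[cl].push_back(idx);
  }

  void classDetach(int idx) {
    Chain& c = chains[idx];
    if (c.cls < 0) return;
    int cl = c.cls;
    std::vector<int>& mem = clsMembers[cl];
    int last = mem.back();
    mem[c.posCls] = last;
    chains[last].posCls = c.posCls;
    mem.pop_back();
    if (mem.empty()) {
      int lastCls = nonempty.back();
      nonempty[posNE[cl]] = lastCls;
      posNE[lastCls] = posNE[cl];
      nonempty.pop_back();
      posNE[cl] = -1;
    }
    c.cls = -1;
    conDelta(c, -1.0); // pairs against members remaining after removal
  }

  // ---- depolymerization bookkeeping ---------------------------------
  int minDyadOf(const Chain& c) const {
    int best = -1;
    for (int d = 0; d < 4; ++d) {
      if (c.m[d] > 0 && (best < 0 || rank[d] < rank[best])) best = d;
    }
    return best;
  }

  void depAttach(int idx) {
    Chain& c = chains[idx];
    int dm = minDyadOf(c);
    c.minDyad = dm;
    if (dm < 0) return;
    c.posMin = (int)byMin[dm].size();
    byMin[dm].push_back(idx);
    for (int d = 0; d < 4; ++d) G[dm][d] += c.m[d];
    if (c.nBonds() > capBonds) capBonds = c.nBonds();
  }

  void depDetach(int idx) {
    Chain& c = chains[idx];
    int dm = c.minDyad;
    if (dm < 0) return;
    std::vector<int>& lst = byMin[dm];
    int last = lst.back();
    lst[c.posMin] = last;
    chains[last].posMin = c.posMin;
    lst.pop_back();
    for (int d = 0; d < 4; ++d) G[dm][d] -= c.m[d];
    c.minDyad = -1;
  }

  // ---- registry attach/detach ---------------------------------------
  void attach(int idx) {
    Chain& c = chains[idx];
    int p = c.phase;
    c.posPhase = (int)phaseList[p].size();
    phaseList[p].push_back(idx);
    Agg& a = agg[p];
    a.n += 1;
    a.sumMW += c.mw;
    a.sumMW2 += c.mw * c.mw;
    a.units += c.nUnits();
    a.sCount += c.sCount;
    if (p == 1) {
      sumFs += c.fS();
      depAttach(idx);
      classAttach(idx);
    }
  }

  void detach(int idx) {
    Chain& c = chains[idx];
    int p = c.phase;
    std::vector<int>& lst = phaseList[p];
    int last = lst.back();
    lst[c.posPhase] = last;
    chains[last].posPhase = c.posPhase;
    lst.pop_back();
    c.posPhase = -1;
    Agg& a = agg[p];
    a.n -= 1;
    a.sumMW -= c.mw;
    a.sumMW2 -= c.mw * c.mw;
    a.units -= c.nUnits();
    a.sCount -= c.sCount;
    if (p == 1) {
      sumFs -= c.fS();
      depDetach(idx);
      classDetach(idx);
    }
  }

  // ---- kinetics cache ------------------------------------------------
  void refreshKinetics() {
    Tcache = Tf;
    dEth = P.Rgas * Tcache * std::log(P.ratio_cutoff) / 1000.0;
    int oldRank[4];
    for (int d = 0; d < 4; ++d) oldRank[d] = rank[d];
    for (int d = 0; d < 4; ++d) {
      Ecur[d] = edepAt(d, Tcache);
      kdep[d] = arrh(P.A_dep, Ecur[d], Tcache);
      if (kdep[d] == 0.0 && Ecur[d] > 0.0) underflow += 1;
    }
    // rank dyads by energy (stable: ties broken by index)
    int ord[4] = {0, 1, 2, 3};
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b)
        if (Ecur[ord[b]] < Ecur[ord[a]]) std::swap(ord[a], ord[b]);
    for (int r = 0; r < 4; ++r) rank[ord[r]] = r;
    for (int dm = 0; dm < 4; ++dm)
      for (int d = 0; d < 4; ++d)
        retain[dm][d] = !filtered || (Ecur[d] <= Ecur[dm] + dEth);
    mwLo = P.vertex_mw - dEth / P.slope_lo;
    mwHi = P.vertex_mw + dEth / P.slope_hi;
    kdem_c = arrh(P.A_dem, P.E_dem, Tcache);
    bool rankChanged = false;
    for (int d = 0; d < 4; ++d) if (rank[d] != oldRank[d]) rankChanged = true;
    if (rankChanged) rebuildDep();
    recomputeCon();
  }

  void ensureKinetics() {
    if (Tcache < 0 || std::fabs(Tf - Tcache) > P.temp_tol) refreshKinetics();
  }

  void rebuildDep() {
    for (int d = 0; d < 4; ++d) byMin[d].clear();
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) G[a][b] = 0;
    capBonds = 1;
    for (size_t k = 0; k < phaseList[1].size(); ++k) {
      chains[phaseList[1][k]].minDyad = -1;
      depAttach(phaseList[1][k]);
    }
  }

  void recomputeCon() {
    rcon = 0.0;
    retPairs = 0.0;
    double C2 = conc() * conc();
    for (size_t ia = 0; ia < nonempty.size(); ++ia) {
      int a = nonempty[ia];
      double na = (double)clsMembers[a].size();
      for (size_t ib = ia; ib < nonempty.size(); ++ib) {
        int b = nonempty[ib];
        double nb = (double)clsMembers[b].size();
        double mwSum = clsMW[a] + clsMW[b];
        if (!pairRetained(mwSum)) continue;
        double np = (a == b) ? na * (na - 1.0) / 2.0 : na * nb;
        if (np <= 0) continue;
        rcon += C2 * kcon(mwSum) * np;
        retPairs += np;
      }
    }
  }

  double rdepTot() const {
    double s = 0.0;
    for (int dm = 0; dm < 4; ++dm)
      for (int d = 0; d < 4; ++d)
        if (retain[dm][d] && G[dm][d] > 0) s += G[dm][d] * kdep[d];
    return s * conc();
  }

  double rdemTot() const { return kdem_c * conc() * (sumFs > 0 ? sumFs : 0.0); }

  double rconTot() const { return rcon > 0 ? rcon : 0.0; }

  double rtot() { return rdepTot() + rdemTot() + rconTot(); }

  // ---- chain constructors -------------------------------------------
  void recomputeDerived(Chain& c) {
    c.sCount = 0;
    for (size_t i = 0; i < c.units.size(); ++i) c.sCount += c.units[i];
    c.dyads.assign(c.units.size() > 0 ? c.units.size() - 1 : 0, 0);
    for (int d = 0; d < 4; ++d) c.m[d] = 0;
    for (size_t i = 0; i + 1 < c.units.size(); ++i) {
      uint8_t d = (uint8_t)((c.units[i] << 1) | c.units[i + 1]);
      c.dyads[i] = d;
      c.m[d] += 1;
    }
    c.mw = c.sCount * P.mwS + (c.nUnits() - c.sCount) * P.mwG;
  }

  int newChain(const std::vector<uint8_t>& units, int phase) {
    Chain c;
    c.id = nextId++;
    c.units = units;
    c.phase = phase;
    c.alive = true;
    recomputeDerived(c);
    chains.push_back(std::move(c));
    int idx = (int)chains.size() - 1;
    id2idx[chains[idx].id] = idx;
    attach(idx);
    return idx;
  }

  void killChain(int idx) {
    detach(idx);
    chains[idx].alive = false;
    id2idx.erase(chains[idx].id);
    chains[idx].units.clear();
    chains[idx].dyads.clear();
  }

  int idxOf(int id) const {
    auto it = id2idx.find(id);
    if (it == id2idx.end()) stop("unknown chain id %d", id);
    return it->second;
  }

  // ---- events --------------------------------------------------------
  void logEvent(int kind, int a, int b, double dt) {
    if (!logOn) return;
    logKind.push_back(kind);
    logA.push_back(a);
    logB.push_back(b);
    logT.push_back(clock);
    logDt.push_back(dt);
  }

  // scission of bond m (0-based) -> ids of the two fragments
  std::pair<int, int> doScission(int idx, int m) {
    Chain& c = chains[idx];
    if (c.phase != 1) stop("scission requires a liquor-phase chain");
    if (m < 0 || m >= c.nBonds()) stop("bond index out of range");
    std::vector<uint8_t> left(c.units.begin(), c.units.begin() + m + 1);
    std::vector<uint8_t> right(c.units.begin() + m + 1, c.units.end());
    killChain(idx);
    int li = newChain(left, 1);
    int ri = newChain(right, 1);
    evDep += 1;
    return std::make_pair(chains[li].id, chains[ri].id);
  }

  int doCondensation(int ia, int ib) {
    if (ia == ib) stop("condensation requires two distinct chains");
    Chain& a = chains[ia];
    Chain& b = chains[ib];
    if (a.phase != 1 || b.phase != 1) stop("condensation requires liquor-phase chains");
    std::vector<uint8_t> merged(a.units);
    merged.insert(merged.end(), b.units.begin(), b.units.end());
    killChain(ia);
    killChain(ib);
    int mi = newChain(merged, 1);
    evCon += 1;
    return chains[mi].id;
  }

  void doDemethoxylation(int idx, int u) {
    Chain& c = chains[idx];
    if (c.phase != 1) stop("demethoxylation requires a liquor-phase chain");
    if (u < 0 || u >= c.nUnits()) stop("unit index out of range");
    if (c.units[u] != 1) stop("unit is not an S unit");
    detach(idx);
    c.units[u] = 0;
    recomputeDerived(c);
    attach(idx);
    evDem += 1;
  }

  // ---- Gillespie selection ------------------------------------------
  int pickDepChain(int dm, int d) {
    std::vector<int>& lst = byMin[dm];
    int n = (int)lst.size();
    for (int tries = 0; tries < 100000; ++tries) {
      int idx = lst[(int)(unif_rand() * n) % n];
      int m = chains[idx].m[d];
      if (m > 0 && unif_rand() * capBonds < m) return idx;
    }
    // deterministic fallback: weighted scan
    double tot = 0;
    for (int k = 0; k < n; ++k) tot += chains[lst[k]].m[d];
    double u = unif_rand() * tot, cum = 0;
    for (int k = 0; k < n; ++k) {
      cum += chains[lst[k]].m[d];
      if (u < cum) return lst[k];
    }
    return lst[n - 1];
  }

  int pickBond(const Chain& c, int d) {
    int r = (int)(unif_rand() * c.m[d]) % c.m[d];
    for (int i = 0; i < c.nBonds(); ++i) {
      if (c.dyads[i] == d) {
        if (r == 0) return i;
        --r;
      }
    }
    return c.nBonds() - 1;
  }

  int pickDemChain() {
    std::vector<int>& lst = phaseList[1];
    int n = (int)lst.size();
    for (int tries = 0; tries < 1000000; ++tries) {
      int idx = lst[(int)(unif_rand() * n) % n];
      double f = chains[idx].fS();
      if (f > 0 && unif_rand() < f) return idx;
    }
    double u = unif_rand() * sumFs, cum = 0;
    for (int k = 0; k < n; ++k) {
      cum += chains[lst[k]].fS();
      if (u < cum) return lst[k];
    }
    return lst[n - 1];
  }

  int pickSUnit(const Chain& c) {
    int r = (int)(unif_rand() * c.sCount) % c.sCount;
    for (int i = 0; i < c.nUnits(); ++i) {
      if (c.units[i] == 1) {
        if (r == 0) return i;
        --r;
      }
    }
    return c.nUnits() - 1;
  }

  void selectAndExecute(double rt, double dtDrawn) {
    double u = unif_rand() * rt;
    // depolymerization block
    double C = conc();
    for (int dm = 0; dm < 4; ++dm) {
      for (int d = 0; d < 4; ++d) {
        if (!retain[dm][d] || G[dm][d] <= 0) continue;
        double w = G[dm][d] * kdep[d] * C;
        if (u < w) {
          int idx = pickDepChain(dm, d);
          int bond = pickBond(chains[idx], d);
          int id = chains[idx].id;
          logEvent(0, id, bond, dtDrawn);
          doScission(idx, bond);
          return;
        }
        u -= w;
      }
    }
    // demethoxylation block
    double rdm = rdemTot();
    if (u < rdm && rdm > 0) {
      int idx = pickDemChain();
      int unit = pickSUnit(chains[idx]);
      logEvent(2, chains[idx].id, unit, dtDrawn);
      doDemethoxylation(idx, unit);
      return;
    }
    u -= rdm;
    // condensation block: walk class pairs in deterministic order
    double C2 = C * C;
    int lastA = -1, lastB = -1;
    for (size_t ia = 0; ia < nonempty.size(); ++ia) {
      int a = nonempty[ia];
      double na = (double)clsMembers[a].size();
      for (size_t ib = ia; ib < nonempty.size(); ++ib) {
        int b = nonempty[ib];
        double nb = (double)clsMembers[b].size();
        double mwSum = clsMW[a] + clsMW[b];
        if (!pairRetained(mwSum)) continue;
        double np = (a == b) ? na * (na - 1.0) / 2.0 : na * nb;
        if (np <= 0) continue;
        lastA = a;
        lastB = b;
        double w = C2 * kcon(mwSum) * np;
        if (u < w) { executeConPair(a, b, dtDrawn); return; }
        u -= w;
      }
    }
    // float drift fallback: fire the last admissible condensation pair
    if (lastA >= 0) { executeConPair(lastA, lastB, dtDrawn); return; }
    // nothing admissible (pure rounding artifact): no-op is not allowed,
    // so treat as demethoxylation if possible, else scission of min bond
    if (rdm > 0) {
      int idx = pickDemChain();
      int unit = pickSUnit(chains[idx]);
      logEvent(2, chains[idx].id, unit, dtDrawn);
      doDemethoxylation(idx, unit);
    }
  }

  void executeConPair(int a, int b, double dtDrawn) {
    int ia, ib;
    if (a == b) {
      int n = (int)clsMembers[a].size();
      int i1 = (int)(unif_rand() * n) % n;
      int i2 = (int)(unif_rand() * (n - 1)) % (n - 1);
      if (i2 >= i1) ++i2;
      ia = clsMembers[a][i1];
      ib = clsMembers[a][i2];
    } else {
      int na = (int)clsMembers[a].size(), nb = (int)clsMembers[b].size();
      ia = clsMembers[a][(int)(unif_rand() * na) % na];
      ib = clsMembers[b][(int)(unif_rand() * nb) % nb];
    }
    logEvent(1, chains[ia].id, chains[ib].id, dtDrawn);
    doCondensation(ia, ib);
  }

  // executes micro events within dt; returns number executed
  int microInterval(double dt) {
    ensureKinetics();
    double t = 0.0;
    int nev = 0;
    for (;;) {
      double rt = rtot();
      if (rt <= 0) break;
      double step = -std::log(unif_rand()) / rt;
      if (t + step > dt) break; // boundary event deferred, not executed
      t += step;
      selectAndExecute(rt, step);
      ++nev;
      if (nev % 16384 == 0) { // refresh rejection-sampling bound
        capBonds = 1;
        for (size_t k = 0; k < phaseList[1].size(); ++k) {
          int nb = chains[phaseList[1][k]].nBonds();
          if (nb > capBonds) capBonds = nb;
        }
      }
    }
    return nev;
  }

  // ---- macro ---------------------------------------------------------
  void doTransfers() {
    ensureKinetics();
    std::vector<int> elig;
    // dissolution: chip -> liquor
    while (!phaseList[0].empty() && accDis >= massScale * P.mwG) {
      elig.clear();
      for (size_t k = 0; k < phaseList[0].size(); ++k) {
        int idx = phaseList[0][k];
        if (massScale * chains[idx].mw <= accDis) elig.push_back(idx);
      }
      if (elig.empty()) break;
      int idx = elig[(int)(unif_rand() * elig.size()) % elig.size()];
      accDis -= massScale * chains[idx].mw;
      detach(idx);
      chains[idx].phase = 1;
      attach(idx);
      nTransD += 1;
    }
    // redeposition: liquor -> chip
    while (!phaseList[1].empty() && accRed >= massScale * P.mwG) {
      elig.clear();
      for (size_t k = 0; k < phaseList[1].size(); ++k) {
        int idx = phaseList[1][k];
        if (massScale * chains[idx].mw <= accRed) elig.push_back(idx);
      }
      if (elig.empty()) break;
      int idx = elig[(int)(unif_rand() * elig.size()) % elig.size()];
      accRed -= massScale * chains[idx].mw;
      detach(idx);
      chains[idx].phase = 0;
      attach(idx);
      nTransR += 1;
    }
  }

  void macroStep(double Text, double Mdot, bool micro) {
    double kD = arrh(P.A_D, P.E_D, Tc);
    double kR = arrh(P.A_R, P.E_R, Tf);
    double rD = kD * Lc - kR * Ld;
    double dis = P.dt * kD * Lc;
    double red = P.dt * kR * Ld;
    Lc += red - dis;
    Ld += dis - red;
    if (Lc < 0) { Ld += Lc; Lc = 0; }
    if (Ld < 0) { Lc += Ld; Ld = 0; }
    accDis += dis;
    accRed += red;
    double Tc2 = Tc + P.dt * (P.dHR * rD + P.U * (Tf - Tc)) / (P.CPc * P.M_c);
    double Tf2 = Tf + P.dt * (-P.U * (Tf - Tc) + P.CPext * Mdot * (Text - Tf)) / (P.CPf * P.M_f);
    if (!std::isfinite(Tc2) || !std::isfinite(Tf2))
      stop("energy balance diverged; reduce dt or check thermal parameters");
    Tc = Tc2;
    Tf = Tf2;
    doTransfers();
    if (micro) microInterval(P.dt);
    clock += P.dt;
    // candidate bookkeeping (full vs retained event counts)
    double nL = agg[1].n;
    double bondsL = agg[1].units - agg[1].n;
    candDep += bondsL > 0 ? bondsL : 0;
    candCon += nL > 1 ? nL * (nL - 1) / 2.0 : 0;
    candDem += nL;
    double rd = 0;
    for (int dm = 0; dm < 4; ++dm)
      for (int d = 0; d < 4; ++d)
        if (retain[dm][d]) rd += G[dm][d];
    retDep += rd;
    retConC += retPairs > 0 ? retPairs : 0;
    stepCount += 1;
  }
};

typedef XPtr<Sim> SimPtr;

// ---- construction ----------------------------------------------------

static void parseParams(Sim& s, List cfg) {
  Params& P = s.P;
  List kin = cfg["kinetics"];
  P.mwS = as<double>(kin["mw_s"]);
  P.mwG = as<double>(kin["mw_g"]);
  P.A_dep = as<double>(kin["a_dep"]);
  P.A_con = as<double>(kin["a_con"]);
  P.A_dem = as<double>(kin["a_dem"]);
  P.E_dem = as<double>(kin["e_dem"]);
  P.Rgas = as<double>(kin["r_gas"]);
  P.omega = as<double>(kin["omega"]);
  DataFrame tab = as<DataFrame>(kin["e_dep_table"]);
  // table: columns dyad (GG/GS/SG/SS), temperature_K, e_dep_kj_mol
  CharacterVector dy = tab["dyad"];
  NumericVector tt = tab["temperature_K"];
  NumericVector ee = tab["e_dep_kj_mol"];
  std::vector<double> temps;
  for (int i = 0; i < tt.size(); ++i) {
    bool seen = false;
    for (size_t j = 0; j < temps.size(); ++j) if (temps[j] == tt[i]) seen = true;
    if (!seen) temps.push_back(tt[i]);
  }
  std::sort(temps.begin(), temps.end());
  P.tabT = temps;
  P.tabE.assign(temps.size(), std::array<double, 4>());
  std::vector<std::array<bool, 4> > got(temps.size(), std::array<bool, 4>());
  for (size_t t = 0; t < temps.size(); ++t)
    for (int d = 0; d < 4; ++d) got[t][d] = false;
  for (int i = 0; i < tt.size(); ++i) {
    std::string d = as<std::string>(dy[i]);
    int dc = d == "GG" ? 0 : d == "GS" ? 1 : d == "SG" ? 2 : d == "SS" ? 3 : -1;
    if (dc < 0) stop("unknown dyad '%s' in e_dep_table", d.c_str());
    size_t tpos = 0;
    while (temps[tpos] != tt[i]) ++tpos;
    P.tabE[tpos][dc] = ee[i];
    got[tpos][dc] = true;
  }
  for (size_t t = 0; t < temps.size(); ++t)
    for (int d = 0; d < 4; ++d)
      if (!got[t][d]) stop("e_dep_table is missing a dyad at %g K", temps[t]);
  List ec = kin["e_con"];
  P.vertex_mw = as<double>(ec["vertex_mw"]);
  P.e_min = as<double>(ec["e_min"]);
  P.slope_lo = as<double>(ec["slope_low"]);
  P.slope_hi = as<double>(ec["slope_high"]);
  List fl = cfg["filter"];
  P.ratio_cutoff = as<double>(fl["ratio_cutoff"]);
  P.max_cond_units = as<int>(fl["max_cond_units"]);
  s.filtered = as<std::string>(cfg["engine"]) == "filtered";
  List mac = cfg["macro"];
  P.A_D = as<double>(mac["a_d"]);
  P.E_D = as<double>(mac["e_d"]);
  P.A_R = as<double>(mac["a_r"]);
  P.E_R = as<double>(mac["e_r"]);
  P.M_c = as<double>(mac["m_c"]);
  P.M_f = as<double>(mac["m_f"]);
  P.CPc = as<double>(mac["cp_c"]);
  P.CPf = as<double>(mac["cp_f"]);
  P.CPext = as<double>(mac["cp_ext"]);
  P.U = as<double>(mac["u"]);
  P.dHR = as<double>(mac["dh_r"]);
  P.dt = as<double>(mac["dt"]);
  P.Lc0 = as<double>(mac["l_c0"]);
  P.temp_tol = as<double>(mac["temp_refresh_tol"]);
}

// [[Rcpp::export]]
SEXP sim_create(List cfg, double temperature) {
  Sim* s = new Sim();
  parseParams(*s, cfg);
  s->Tc = temperature;
  s->Tf = temperature;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) { s->G[a][b] = 0; s->retain[a][b] = true; }
  for (int d = 0; d < 4; ++d) s->rank[d] = d;
  s->refreshKinetics();
  return SimPtr(s, true);
}

// [[Rcpp::export]]
void sim_populate(SEXP xp, int n_chains, double target_mn, double target_sg) {
  Sim& s = *SimPtr(xp);
  if (n_chains < 1) stop("n_chains must be at least 1");
  double pS = target_sg / (1.0 + target_sg);
  double mu = pS * s.P.mwS + (1.0 - pS) * s.P.mwG;
  if (target_mn < s.P.mwG) stop("target_mn below the mass of a single G unit");
  double lambda = target_mn / mu;
  for (int i = 0; i < n_chains; ++i) {
    int len = 1 + (int)R::rpois(std::max(lambda - 1.0, 0.0));
    std::vector<uint8_t> u(len);
    for (int k = 0; k < len; ++k) u[k] = unif_rand() < pS ? 1 : 0;
    s.newChain(u, 0);
  }
  s.Lc = s.P.Lc0;
  s.Ld = 0.0;
  if (s.agg[0].sumMW > 0) s.massScale = s.P.Lc0 / s.agg[0].sumMW;
}

// [[Rcpp::export]]
int sim_add_chain(SEXP xp, std::string seq, std::string phase) {
  Sim& s = *SimPtr(xp);
  if (seq.empty()) stop("sequence must contain at least one unit");
  std::vector<uint8_t> u(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    if (seq[i] == 'S') u[i] = 1;
    else if (seq[i] == 'G') u[i] = 0;
    else stop("sequence characters must be 'S' or 'G'");
  }
  int ph = phase == "chip" ? 0 : 1;
  int idx = s.newChain(u, ph);
  return s.chains[idx].id;
}

// [[Rcpp::export]]
SEXP sim_clone(SEXP xp) {
  Sim& s = *SimPtr(xp);
  Sim* t = new Sim(s);
  // compact: drop dead chains, rebuild all index structures
  std::vector<Chain> live;
  live.reserve(s.id2idx.size());
  for (size_t i = 0; i < t->chains.size(); ++i)
    if (t->chains[i].alive) live.push_back(t->chains[i]);
  t->chains = live;
  t->id2idx.clear();
  t->phaseList[0].clear();
  t->phaseList[1].clear();
  for (int d = 0; d < 4; ++d) t->byMin[d].clear();
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) t->G[a][b] = 0;
  t->clsIndex.clear();
  t->clsS.clear(); t->clsG.clear(); t->clsMW.clear();
  t->clsMembers.clear();
  t->nonempty.clear(); t->posNE.clear();
  t->agg[0] = Agg();
  t->agg[1] = Agg();
  t->sumFs = 0;
  t->rcon = 0;
  t->retPairs = 0;
  t->capBonds = 1;
  for (size_t i = 0; i < t->chains.size(); ++i) {
    t->id2idx[t->chains[i].id] = (int)i;
    t->chains[i].posPhase = t->chains[i].posMin = t->chains[i].posCls = -1;
    t->chains[i].minDyad = t->chains[i].cls = -1;
    t->attach((int)i);
  }
  t->recomputeCon();
  return SimPtr(t, true);
}

// Down-sample a simulation to about `target` chains (state-matched reduced
// replica for MPC rollouts).  The replica is an f-scale miniature reactor:
// extensive macroscale quantities (lignin masses, phase masses, transfer
// accumulators, heat-exchange terms) shrink by the sampling fraction f
// while the per-chain mass quantum stays untouched, so intensive dynamics
// -- including the granularity of chain transfer -- match the parent.
// The second-order condensation channel sees f-fold fewer partners and is
// compensated through its pre-exponential.
// [[Rcpp::export]]
SEXP sim_reduce(SEXP xp, int target) {
  Sim& s = *SimPtr(xp);
  std::vector<int> alive;
  for (size_t i = 0; i < s.chains.size(); ++i)
    if (s.chains[i].alive) alive.push_back((int)i);
  int n = (int)alive.size();
  int m = target < n ? target : n;
  // partial Fisher-Yates draw of m distinct chains
  for (int k = 0; k < m; ++k) {
    int j = k + (int)(unif_rand() * (n - k)) % (n - k);
    std::swap(alive[k], alive[j]);
  }
  double f = n > 0 ? (double)m / (double)n : 1.0;
  Sim* t = new Sim();
  t->P = s.P;
  t->P.A_con = s.P.A_con / f;
  t->P.Lc0 = s.P.Lc0 * f;
  t->P.M_c = s.P.M_c * f;
  t->P.M_f = s.P.M_f * f;
  t->P.U = s.P.U * f;
  t->P.CPext = s.P.CPext * f;
  t->filtered = s.filtered;
  t->Lc = s.Lc * f; t->Ld = s.Ld * f; t->Tc = s.Tc; t->Tf = s.Tf;
  t->clock = s.clock;
  t->accDis = s.accDis * f; t->accRed = s.accRed * f;
  t->massScale = s.massScale;
  t->nextId = 1;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) { t->G[a][b] = 0; t->retain[a][b] = true; }
  for (int d = 0; d < 4; ++d) t->rank[d] = d;
  t->refreshKinetics();
  for (int k = 0; k < m; ++k) {
    const Chain& c = s.chains[alive[k]];
    int idx = t->newChain(c.units, c.phase);
    (void)idx;
  }
  t->refreshKinetics();
  return SimPtr(t, true);
}

// ---- accessors -------------------------------------------------------

// [[Rcpp::export]]
List sim_state(SEXP xp) {
  Sim& s = *SimPtr(xp);
  return List::create(
    _["t_c"] = s.Tc, _["t_f"] = s.Tf, _["clock"] = s.clock,
    _["l_c"] = s.Lc, _["l_d"] = s.Ld,
    _["acc_dissolve"] = s.accDis, _["acc_redeposit"] = s.accRed,
    _["mass_scale"] = s.massScale,
    _["delta_e_th"] = s.dEth, _["mw_low"] = s.mwLo, _["mw_high"] = s.mwHi,
    _["engine"] = s.filtered ? "filtered" : "full");
}

// [[Rcpp::export]]
void sim_set(SEXP xp, std::string name, double value) {
  Sim& s = *SimPtr(xp);
  if (name == "t_c") s.Tc = value;
  else if (name == "t_f") { s.Tf = value; s.refreshKinetics(); }
  else if (name == "l_c") s.Lc = value;
  else if (name == "l_d") s.Ld = value;
  else if (name == "acc_dissolve") s.accDis = value;
  else if (name == "acc_redeposit") s.accRed = value;
  else if (name == "mass_scale") s.massScale = value;
  else stop("unknown state field '%s'", name.c_str());
}

// [[Rcpp::export]]
List sim_aggregates(SEXP xp) {
  Sim& s = *SimPtr(xp);
  List out(2);
  CharacterVector nm = CharacterVector::create("chip", "liquor");
  for (int p = 0; p < 2; ++p) {
    out[p] = List::create(
      _["n_chains"] = s.agg[p].n, _["sum_mw"] = s.agg[p].sumMW,
      _["sum_mw2"] = s.agg[p].sumMW2, _["units"] = s.agg[p].units,
      _["s_count"] = s.agg[p].sCount);
  }
  out.attr("names") = nm;
  List res = List::create(_["chip"] = out[0], _["liquor"] = out[1],
                          _["sum_fs"] = s.sumFs);
  return res;
}

// [[Rcpp::export]]
List sim_observables_cpp(SEXP xp, std::string phase) {
  Sim& s = *SimPtr(xp);
  int p = phase == "chip" ? 0 : 1;
  Agg& a = s.agg[p];
  double mn = NA_REAL, mw = NA_REAL, sg = NA_REAL;
  if (a.n > 0) {
    mn = a.sumMW / a.n;
    mw = a.sumMW2 / a.sumMW;
  }
  double gCount = a.units - a.sCount;
  if (a.units > 0) sg = gCount > 0 ? a.sCount / gCount : R_PosInf;
  return List::create(_["mn"] = mn, _["mw"] = mw, _["sg_ratio"] = sg,
                      _["n_chains"] = a.n);
}

// [[Rcpp::export]]
DataFrame sim_snapshot(SEXP xp) {
  Sim& s = *SimPtr(xp);
  int n = (int)s.id2idx.size();
  IntegerVector id(n), sCount(n), nBonds(n);
  CharacterVector phase(n), seq(n);
  NumericVector mw(n), eLow(n);
  s.ensureKinetics();
  int k = 0;
  for (size_t i = 0; i < s.chains.size(); ++i) {
    const Chain& c = s.chains[i];
    if (!c.alive) continue;
    id[k] = c.id;
    phase[k] = c.phase == 0 ? "chip" : "liquor";
    std::string str(c.units.size(), 'G');
    for (size_t j = 0; j < c.units.size(); ++j) if (c.units[j]) str[j] = 'S';
    seq[k] = str;
    mw[k] = c.mw;
    sCount[k] = c.sCount;
    nBonds[k] = c.nBonds();
    double el = NA_REAL;
    for (int d = 0; d < 4; ++d)
      if (c.m[d] > 0 && (!R_finite(el) || s.Ecur[d] < el)) el = s.Ecur[d];
    eLow[k] = el;
    ++k;
  }
  return DataFrame::create(_["id"] = id, _["phase"] = phase, _["sequence"] = seq,
                           _["mw"] = mw, _["s_count"] = sCount,
                           _["n_bonds"] = nBonds, _["e_low"] = eLow,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
NumericVector sim_bond_energies(SEXP xp, int id) {
  Sim& s = *SimPtr(xp);
  s.ensureKinetics();
  const Chain& c = s.chains[s.idxOf(id)];
  NumericVector out(c.nBonds());
  for (int i = 0; i < c.nBonds(); ++i) out[i] = s.Ecur[c.dyads[i]];
  return out;
}

// ---- event application ----------------------------------------------

// [[Rcpp::export]]
IntegerVector sim_apply_scission(SEXP xp, int id, int bond) {
  Sim& s = *SimPtr(xp);
  s.ensureKinetics();
  std::pair<int, int> r = s.doScission(s.idxOf(id), bond);
  return IntegerVector::create(r.first, r.second);
}

// [[Rcpp::export]]
int sim_apply_condensation(SEXP xp, int id_i, int id_j) {
  Sim& s = *SimPtr(xp);
  s.ensureKinetics();
  if (id_i == id_j) stop("condensation requires two distinct chains (j != i)");
  return s.doCondensation(s.idxOf(id_i), s.idxOf(id_j));
}

// [[Rcpp::export]]
void sim_apply_demethoxylation(SEXP xp, int id, int unit) {
  Sim& s = *SimPtr(xp);
  s.ensureKinetics();
  s.doDemethoxylation(s.idxOf(id), unit);
}

// [[Rcpp::export]]
int sim_transfer(SEXP xp, std::string direction) {
  // manual single transfer; returns moved chain id, or 0 when none eligible
  Sim& s = *SimPtr(xp);
  s.ensureKinetics();
  int src = direction == "dissolve" ? 0 : 1;
  double& acc = direction == "dissolve" ? s.accDis : s.accRed;
  std::vector<int> elig;
  for (size_t k = 0; k < s.phaseList[src].size(); ++k) {
    int idx = s.phaseList[src][k];
    if (s.massScale * s.chains[idx].mw <= acc) elig.push_back(idx);
  }
  if (elig.empty()) return 0;
  int idx = elig[(int)(unif_rand() * elig.size()) % elig.size()];
  acc -= s.massScale * s.chains[idx].mw;
  s.detach(idx);
  s.chains[idx].phase = 1 - src;
  s.attach(idx);
  if (src == 0) s.nTransD += 1; else s.nTransR += 1;
  return s.chains[idx].id;
}

// ---- catalogs and rates ---------------------------------------------

// [[Rcpp::export]]
double sim_rtot(SEXP xp) {
  Sim& s = *SimPtr(xp);
  s.ensureKinetics();
  return s.rtot();
}

// [[Rcpp::export]]
NumericVector sim_rtot_parts(SEXP xp) {
  Sim& s = *SimPtr(xp);
  s.ensureKinetics();
  return NumericVector::create(_["depolymerization"] = s.rdepTot(),
                               _["condensation"] = s.rconTot(),
                               _["demethoxylation"] = s.rdemTot());
}

// Brute-force enumerated catalog (per-bond, per-pair, per-chain events).
// Intended as an oracle on small systems: condensation enumeration is
// quadratic in the liquor population.
// [[Rcpp::export]]
DataFrame sim_catalog(SEXP xp, bool apply_filter) {
  Sim& s = *SimPtr(xp);
  s.ensureKinetics();
  std::vector<std::string> kind;
  std::vector<int> ci, cj;
  std::vector<double> en, prop;
  double C = s.conc();
  std::vector<int>& lst = s.phaseList[1];
  for (size_t k = 0; k < lst.size(); ++k) {
    const Chain& c = s.chains[lst[k]];
    // depolymerization: one event per retained bond
    if (c.nBonds() > 0) {
      double eLow = R_PosInf;
      for (int d = 0; d < 4; ++d)
        if (c.m[d] > 0 && s.Ecur[d] < eLow) eLow = s.Ecur[d];
      for (int b = 0; b < c.nBonds(); ++b) {
        double E = s.Ecur[c.dyads[b]];
        if (apply_filter && E > eLow + s.dEth) continue;
        kind.push_back("depolymerization");
        ci.push_back(c.id);
        cj.push_back(b + 1);
        en.push_back(E);
        prop.push_back(s.arrh(s.P.A_dep, E, s.Tcache) * C);
      }
    }
    // demethoxylation: one event per chain with S content
    if (c.sCount > 0) {
      kind.push_back("demethoxylation");
      ci.push_back(c.id);
      cj.push_back(NA_INTEGER);
      en.push_back(s.P.E_dem);
      prop.push_back(s.kdem_c * c.fS() * C);
    }
  }
  // condensation: unordered pairs
  for (size_t a = 0; a < lst.size(); ++a) {
    for (size_t b = a + 1; b < lst.size(); ++b) {
      const Chain& x = s.chains[lst[a]];
      const Chain& y = s.chains[lst[b]];
      double mwSum = x.mw + y.mw;
      if (apply_filter && !(mwSum >= s.mwLo && mwSum <= s.mwHi)) continue;
      double E = s.econ(mwSum);
      kind.push_back("condensation");
      ci.push_back(x.id);
      cj.push_back(y.id);
      en.push_back(E);
      prop.push_back(s.arrh(s.P.A_con, E, s.Tcache) * C * C);
    }
  }
  return DataFrame::create(_["kind"] = kind, _["chain_i"] = ci, _["site_or_j"] = cj,
                           _["energy"] = en, _["propensity"] = prop,
                           _["stringsAsFactors"] = false);
}

// ---- runners ---------------------------------------------------------

// [[Rcpp::export]]
List sim_run_micro(SEXP xp, double dt) {
  Sim& s = *SimPtr(xp);
  int n = s.microInterval(dt);
  return List::create(_["n_events"] = n,
                      _["ev_dep"] = s.evDep, _["ev_con"] = s.evCon,
                      _["ev_dem"] = s.evDem);
}

// [[Rcpp::export]]
void sim_macro_step(SEXP xp, double t_ext, double mdot_ext, bool micro) {
  SimPtr(xp)->macroStep(t_ext, mdot_ext, micro);
}

// [[Rcpp::export]]
DataFrame sim_run(SEXP xp, double duration, NumericVector sched_t,
                  NumericVector sched_T, NumericVector sched_F,
                  bool micro, double record_every) {
  Sim& s = *SimPtr(xp);
  long nStep = (long)std::floor(duration / s.P.dt + 0.5);
  std::vector<double> rt, rLc, rLd, rTc, rTf, rTx, rMd, rMn, rMw, rSg, rRt;
  std::vector<double> rNL, rNC, rDepE, rConE, rDemE;
  int sp = 0;
  double nextRec = 0.0;
  double t0 = s.clock;
  for (long k = 0; k <= nStep; ++k) {
    double tRel = k * s.P.dt;
    while (sp + 1 < sched_t.size() && sched_t[sp + 1] <= tRel + 1e-12) ++sp;
    double Tx = sched_T[sp], Md = sched_F[sp];
    if (tRel + 1e-9 >= nextRec || k == nStep) {
      s.ensureKinetics();
      rt.push_back(t0 + tRel);
      rLc.push_back(s.Lc);
      rLd.push_back(s.Ld);
      rTc.push_back(s.Tc);
      rTf.push_back(s.Tf);
      rTx.push_back(Tx);
      rMd.push_back(Md);
      Agg& a = s.agg[1];
      rMn.push_back(a.n > 0 ? a.sumMW / a.n : NA_REAL);
      rMw.push_back(a.n > 0 ? a.sumMW2 / a.sumMW : NA_REAL);
      double g = a.units - a.sCount;
      rSg.push_back(a.units > 0 ? (g > 0 ? a.sCount / g : R_PosInf) : NA_REAL);
      rNL.push_back(a.n);
      rNC.push_back(s.agg[0].n);
      rRt.push_back(s.rtot());
      rDepE.push_back(s.evDep);
      rConE.push_back(s.evCon);
      rDemE.push_back(s.evDem);
      while (nextRec <= tRel + 1e-9) nextRec += record_every;
    }
    if (k == nStep) break;
    s.macroStep(Tx, Md, micro);
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["t_min"] = rt, _["l_c"] = rLc, _["l_d"] = rLd, _["t_c"] = rTc,
    _["t_f"] = rTf, _["t_ext"] = rTx, _["mdot_ext"] = rMd, _["mn"] = rMn,
    _["mw"] = rMw, _["sg_ratio"] = rSg, _["n_liquor"] = rNL, _["n_chip"] = rNC,
    _["r_tot"] = rRt, _["ev_dep"] = rDepE, _["ev_con"] = rConE,
    _["ev_dem"] = rDemE);
}

// ---- counters / log --------------------------------------------------

// [[Rcpp::export]]
List sim_counters(SEXP xp) {
  Sim& s = *SimPtr(xp);
  return List::create(
    _["ev_dep"] = s.evDep, _["ev_con"] = s.evCon, _["ev_dem"] = s.evDem,
    _["n_dissolved"] = s.nTransD, _["n_redeposited"] = s.nTransR,
    _["cand_dep"] = s.candDep, _["cand_con"] = s.candCon,
    _["cand_dem"] = s.candDem, _["ret_dep"] = s.retDep,
    _["ret_con"] = s.retConC, _["macro_steps"] = s.stepCount,
    _["underflow"] = s.underflow);
}

// [[Rcpp::export]]
void sim_log_enable(SEXP xp, bool on) {
  Sim& s = *SimPtr(xp);
  s.logOn = on;
  if (!on) {
    s.logKind.clear(); s.logA.clear(); s.logB.clear();
    s.logT.clear(); s.logDt.clear();
  }
}

// [[Rcpp::export]]
DataFrame sim_event_log(SEXP xp) {
  Sim& s = *SimPtr(xp);
  int n = (int)s.logKind.size();
  CharacterVector kind(n);
  for (int i = 0; i < n; ++i)
    kind[i] = s.logKind[i] == 0 ? "depolymerization"
            : s.logKind[i] == 1 ? "condensation" : "demethoxylation";
  return DataFrame::create(_["t_min"] = NumericVector(s.logT.begin(), s.logT.end()),
                           _["kind"] = kind,
                           _["a"] = IntegerVector(s.logA.begin(), s.logA.end()),
                           _["b"] = IntegerVector(s.logB.begin(), s.logB.end()),
                           _["dt"] = NumericVector(s.logDt.begin(), s.logDt.end()),
                           _["stringsAsFactors"] = false);
}
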