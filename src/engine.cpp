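// Cellular Potts engine for hexagonal-lattice cystogenesis simulation.
//
// The lattice is axial-coordinate hexagonal: site (c, r), 0 <= c < W,
// 0 <= r < H, Cartesian embedding x = c + r/2, y = r*sqrt(3)/2 (unit
// center-to-center distance). Neighbor offsets are listed in cyclic order so
// that consecutive entries are mutually adjacent; lattice triangles are
// exactly the (site, nb_i, nb_{i+1}) triples, which makes tight-junction
// counting a local O(6) operation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const int DC[6] = {1, 0, -1, -1, 0, 1};
static const int DR[6] = {0, 1, 1, 0, -1, -1};
static const double SQRT3_2 = 0.8660254037844386;

enum Kind { KIND_CELL = 0, KIND_LUMEN = 1 };
enum CellState { ST_UNPOL = 0, ST_POL = 1, ST_STAB = 2 };
// adhesion type indices
enum AdhType { TY_MATRIX = 0, TY_UNPOL = 1, TY_POL = 2, TY_STAB = 3,
               TY_DYING = 4, TY_LUMEN = 5 };

struct Obj {
  int kind;
  int state;
  bool dying;
  bool alive;
  int A;
  double TA;
  int P;
  double TP;
  double cycleCounter;
  double polarCounter;
  bool polarStarted;
  double shiftCounter;
  bool shiftStarted;
  double mbx, mby;
  bool hasMidbody;
  int deathStart;
};

struct Par {
  double lambdaArea, lambdaLumen, lambdaPerim;
  double temperature, attemptsFactor, connPenalty;
  double J[6][6];
  double wedgeArea, stableTargetArea, stableAreaSlope;
  double cellCycle, polarDelay, shiftDelay, doublingArea;
  int divisionReg;
  double multiplier, K;
  double lumenGrowthRate, deathRateLumen, deathRateEpi;
  double clusterProb, lgrSubtract, dyingShrinkRate;
  double stableRatio, stableCycleDelay;
};

static Par parseParams(List p) {
  Par q;
  q.lambdaArea = as<double>(p["lambda_area"]);
  q.lambdaLumen = as<double>(p["lambda_lumen"]);
  q.lambdaPerim = as<double>(p["lambda_perim"]);
  q.temperature = as<double>(p["temperature"]);
  q.attemptsFactor = as<double>(p["attempts_factor"]);
  q.connPenalty = as<double>(p["connectivity_penalty"]);
  NumericMatrix J = as<NumericMatrix>(p["adhesion"]);
  if (J.nrow() != 6 || J.ncol() != 6) stop("adhesion matrix must be 6x6");
  for (int i = 0; i < 6; i++)
    for (int j = 0; j < 6; j++) q.J[i][j] = J(i, j);
  q.wedgeArea = as<double>(p["wedge_area"]);
  q.stableTargetArea = as<double>(p["stable_target_area"]);
  q.stableAreaSlope = as<double>(p["stable_area_slope"]);
  q.cellCycle = as<double>(p["cell_cycle"]);
  q.polarDelay = as<double>(p["polar_delay"]);
  q.shiftDelay = as<double>(p["shift_delay"]);
  q.doublingArea = as<double>(p["doubling_area"]);
  q.divisionReg = as<int>(p["division_reg"]);
  q.multiplier = as<double>(p["multiplier"]);
  q.K = as<double>(p["k_perim"]);
  q.lumenGrowthRate = as<double>(p["lumen_growth_rate"]);
  q.deathRateLumen = as<double>(p["death_rate_lumen"]);
  q.deathRateEpi = as<double>(p["death_rate_epi"]);
  q.clusterProb = as<double>(p["cluster_prob"]);
  q.lgrSubtract = as<double>(p["lgr_subtract"]);
  q.dyingShrinkRate = as<double>(p["dying_shrink_rate"]);
  q.stableRatio = as<double>(p["stable_ratio"]);
  q.stableCycleDelay = as<double>(p["stable_cycle_delay"]);
  return q;
}

class Engine {
public:
  int W, H;
  std::vector<int> owner;           // site index = c + r*W; 0 = matrix
  std::vector<Obj> objs;            // 1-based; objs[0] unused
  Par par;
  int cycle;
  bool firstDivisionDone;

  // per-cycle survey caches
  std::vector<std::vector<int>> siteList;
  std::vector<int> matE, lumE, cellE;     // boundary edge counts per object
  std::vector<int> lumenContact;          // per cell: 0 none, lumen id, -1 multiple
                                          // maintained conservatively between
                                          // surveys (contacts are added on
                                          // flips, never dropped mid-cycle)
  std::vector<std::vector<int>> lumNbCells;
  std::vector<std::pair<int,int>> lumenAdjPairs;
  long nonMatrix;
  int extMinC, extMaxC, extMinR, extMaxR;

  // scratch
  std::vector<int> stamp;
  int stampCtr;
  std::vector<int> bfsStack;

  // events
  std::vector<int> evCycle, evId;
  std::vector<std::string> evName;
  std::vector<double> evX, evY;
  long nAttempts, nAccepted;

  Engine() : cycle(0), firstDivisionDone(false), nonMatrix(0), stampCtr(0),
             nAttempts(0), nAccepted(0) {}

  inline int idx(int c, int r) const { return c + r * W; }
  inline bool inField(int c, int r) const {
    return c >= 0 && c < W && r >= 0 && r < H;
  }
  inline int ownerAt(int c, int r) const {
    return inField(c, r) ? owner[idx(c, r)] : 0;
  }
  inline double X(int s) const { return (s % W) + (s / W) * 0.5; }
  inline double Y(int s) const { return (s / W) * SQRT3_2; }

  inline int typeOf(int id) const {
    if (id == 0) return TY_MATRIX;
    const Obj &o = objs[id];
    if (o.kind == KIND_LUMEN) return TY_LUMEN;
    if (o.dying) return TY_DYING;
    return o.state + 1;
  }

  void pushEvent(int cyc, int id, const char *name, double x, double y) {
    evCycle.push_back(cyc); evId.push_back(id); evName.push_back(name);
    evX.push_back(x); evY.push_back(y);
  }

  // ------------------------------------------------------------------ survey
  void survey() {
    int n = (int)objs.size();
    siteList.assign(n, std::vector<int>());
    matE.assign(n, 0); lumE.assign(n, 0); cellE.assign(n, 0);
    lumenContact.assign(n, 0);
    lumNbCells.assign(n, std::vector<int>());
    lumenAdjPairs.clear();
    nonMatrix = 0;
    extMinC = W; extMaxC = -1; extMinR = H; extMaxR = -1;
    std::vector<int> cellMark(n, -1);   // per-lumen dedupe of neighbor cells
    for (int r = 0; r < H; r++) {
      for (int c = 0; c < W; c++) {
        int a = owner[idx(c, r)];
        if (a == 0) continue;
        nonMatrix++;
        if (c < extMinC) extMinC = c;
        if (c > extMaxC) extMaxC = c;
        if (r < extMinR) extMinR = r;
        if (r > extMaxR) extMaxR = r;
        siteList[a].push_back(idx(c, r));
        for (int k = 0; k < 6; k++) {
          int b = ownerAt(c + DC[k], r + DR[k]);
          if (b == a) continue;
          if (b == 0) { matE[a]++; continue; }
          if (objs[b].kind == KIND_LUMEN) {
            lumE[a]++;
            if (objs[a].kind == KIND_CELL) {
              if (lumenContact[a] == 0) lumenContact[a] = b;
              else if (lumenContact[a] != b) lumenContact[a] = -1;
              if (cellMark.size() <= (size_t)b) {}
            } else if (objs[a].kind == KIND_LUMEN && a < b) {
              if (lumenAdjPairs.empty() || lumenAdjPairs.back() !=
                  std::make_pair(a, b))
                lumenAdjPairs.push_back(std::make_pair(a, b));
            }
          } else {
            cellE[a]++;
            if (objs[a].kind == KIND_LUMEN) {
              if (cellMark[b] != a) { cellMark[b] = a; lumNbCells[a].push_back(b); }
            }
          }
        }
      }
    }
  }

  // -------------------------------------------------------------- energetics
  // tight-junction triple: exactly one lumen corner plus two sites in two
  // distinct cells
  inline bool isTJtriple(int a, int b, int c) const {
    int lum = 0, cell1 = 0, cell2 = 0;
    int ids[3] = {a, b, c};
    for (int i = 0; i < 3; i++) {
      int w = ids[i];
      if (w == 0) return false;
      if (objs[w].kind == KIND_LUMEN) { lum++; }
      else { if (!cell1) cell1 = w; else cell2 = w; }
    }
    return lum == 1 && cell1 && cell2 && cell1 != cell2;
  }

  // number of TJ triangles containing site s when s is owned by asOwner
  int tjTriCountAt(int c, int r, int asOwner) const {
    int cnt = 0;
    for (int k = 0; k < 6; k++) {
      int k2 = (k + 1) % 6;
      int c1 = c + DC[k], r1 = r + DR[k];
      int c2 = c + DC[k2], r2 = r + DR[k2];
      if (!inField(c1, r1) || !inField(c2, r2)) continue;
      if (isTJtriple(asOwner, owner[idx(c1, r1)], owner[idx(c2, r2)])) cnt++;
    }
    return cnt;
  }

  // would removing site s from object o disconnect it?
  bool connectivityViolation(int c, int r, int o) {
    int s = idx(c, r);
    bool m[6];
    int cnt = 0;
    for (int k = 0; k < 6; k++) {
      m[k] = (ownerAt(c + DC[k], r + DR[k]) == o);
      if (m[k]) cnt++;
    }
    if (cnt == 0) return objs[o].A > 1;
    int trans = 0;
    for (int k = 0; k < 6; k++) if (m[k] != m[(k + 1) % 6]) trans++;
    if (trans <= 2) return false;   // neighbors in o form one contiguous arc
    // full flood fill over o excluding s
    if ((int)stamp.size() != W * H) stamp.assign(W * H, 0);
    stampCtr++;
    bfsStack.clear();
    int start = -1;
    for (int k = 0; k < 6; k++) {
      if (m[k]) { start = idx(c + DC[k], r + DR[k]); break; }
    }
    bfsStack.push_back(start);
    stamp[start] = stampCtr;
    int seen = 1;
    while (!bfsStack.empty()) {
      int t = bfsStack.back(); bfsStack.pop_back();
      int tc = t % W, tr = t / W;
      for (int k = 0; k < 6; k++) {
        int nc = tc + DC[k], nr = tr + DR[k];
        if (!inField(nc, nr)) continue;
        int u = idx(nc, nr);
        if (u == s || stamp[u] == stampCtr || owner[u] != o) continue;
        stamp[u] = stampCtr;
        seen++;
        bfsStack.push_back(u);
      }
    }
    return seen != objs[o].A - 1;
  }

  // energy change if site (c, r) flips from its owner o to candidate n
  double deltaG(int c, int r, int n, bool bypassTJ) {
    int s = idx(c, r);
    int o = owner[s];
    int inO = 0, inN = 0;
    bool nbMatrix = false, nbLumen = false;
    for (int k = 0; k < 6; k++) {
      int w = ownerAt(c + DC[k], r + DR[k]);
      if (w == o) inO++;
      if (w == n) inN++;
      if (w == 0) nbMatrix = true;
      else if (objs[w].kind == KIND_LUMEN) nbLumen = true;
    }
    double dG = 0.0;
    if (o != 0) {
      const Obj &Oo = objs[o];
      double lam = (Oo.kind == KIND_LUMEN) ? par.lambdaLumen : par.lambdaArea;
      double d0 = Oo.TA - Oo.A, d1 = Oo.TA - (Oo.A - 1);
      if (Oo.A == 1 && Oo.kind == KIND_CELL && Oo.dying) {
        // the dying cell vanishes with this move: its constraint energies
        // disappear with it
        dG -= lam * d0 * d0;
        double e0 = Oo.TP - Oo.P;
        dG -= par.lambdaPerim * e0 * e0;
      } else {
        dG += lam * (d1 * d1 - d0 * d0);
        if (Oo.kind == KIND_CELL) {
          int dP = inO - (6 - inO);
          double e0 = Oo.TP - Oo.P, e1 = Oo.TP - (Oo.P + dP);
          dG += par.lambdaPerim * (e1 * e1 - e0 * e0);
        }
      }
      if (Oo.A == 1) {
        bool mayVanish = (Oo.kind == KIND_LUMEN) || Oo.dying;
        if (!mayVanish) dG += par.connPenalty;
      } else if (connectivityViolation(c, r, o)) {
        dG += par.connPenalty;
      }
    }
    if (n != 0) {
      const Obj &On = objs[n];
      double lam = (On.kind == KIND_LUMEN) ? par.lambdaLumen : par.lambdaArea;
      double d0 = On.TA - On.A, d1 = On.TA - (On.A + 1);
      dG += lam * (d1 * d1 - d0 * d0);
      if (On.kind == KIND_CELL) {
        int dP = (6 - inN) - inN;
        double e0 = On.TP - On.P, e1 = On.TP - (On.P + dP);
        dG += par.lambdaPerim * (e1 * e1 - e0 * e0);
      }
    }
    // adhesion: per-edge contact energy, out-of-field counts as matrix
    int to = typeOf(o), tn = typeOf(n);
    for (int k = 0; k < 6; k++) {
      int w = ownerAt(c + DC[k], r + DR[k]);
      int tw = typeOf(w);
      if (w != o) dG -= par.J[to][tw];
      if (w != n) dG += par.J[tn][tw];
    }
    // a lumen may never touch matrix (tight junctions seal the apical surface)
    if (n != 0 && objs[n].kind == KIND_LUMEN && nbMatrix) dG += par.connPenalty;
    if (n == 0 && nbLumen) dG += par.connPenalty;
    // tight junctions prevent a cell from contacting two lumens: reject
    // moves that would create a second lumen contact (cached contact map).
    // Dying cells are exempt: apoptotic cells lose junctional integrity and
    // are resorbed, transiently touching both lumens they separated.
    if (n != 0 && !lumenContact.empty()) {
      if (objs[n].kind == KIND_LUMEN) {
        for (int k = 0; k < 6; k++) {
          int w = ownerAt(c + DC[k], r + DR[k]);
          if (w != 0 && w != n && objs[w].kind == KIND_CELL &&
              !objs[w].dying) {
            int lc = lumenContact[w];
            if (lc != 0 && lc != n) { dG += par.connPenalty; break; }
          }
        }
      } else if (!objs[n].dying) {
        int lcn = lumenContact[n];
        for (int k = 0; k < 6; k++) {
          int w = ownerAt(c + DC[k], r + DR[k]);
          if (w != 0 && objs[w].kind == KIND_LUMEN) {
            if (lcn != 0 && lcn != w) { dG += par.connPenalty; break; }
            lcn = w;
          }
        }
      }
    }
    // tight-junction integrity: reject index changes that alter the local
    // TJ count (remodeling happens only in the end-of-cycle TJ pass);
    // resorption of dying cells is not gated by TJ integrity
    bool dyingDonor = (o != 0 && objs[o].kind == KIND_CELL && objs[o].dying);
    if (!bypassTJ && !dyingDonor) {
      if (tjTriCountAt(c, r, o) != tjTriCountAt(c, r, n)) dG += par.connPenalty;
    }
    return dG;
  }

  inline bool acceptMove(double dG) {
    double rr = unif_rand();
    if (dG <= 0.0) return rr < 1.0;
    return rr < std::exp(-dG / par.temperature);
  }

  // apply an index change with incremental bookkeeping
  void applyFlip(int c, int r, int n) {
    int s = idx(c, r);
    int o = owner[s];
    int inO = 0, inN = 0;
    for (int k = 0; k < 6; k++) {
      int w = ownerAt(c + DC[k], r + DR[k]);
      if (w == o) inO++;
      if (w == n) inN++;
    }
    owner[s] = n;
    if (o != 0) {
      Obj &Oo = objs[o];
      Oo.A -= 1;
      Oo.P += inO - (6 - inO);
      if (Oo.A == 0) {
        Oo.alive = false;
        Oo.P = 0;
        if (Oo.kind == KIND_CELL && Oo.dying)
          pushEvent(cycle + 1, o, "death_complete", X(s), Y(s));
        else if (Oo.kind == KIND_LUMEN)
          pushEvent(cycle + 1, o, "lumen_removed", X(s), Y(s));
      }
      if (n == 0) nonMatrix--;
    }
    if (n != 0) {
      Obj &On = objs[n];
      On.A += 1;
      On.P += (6 - inN) - inN;
      if (o == 0) nonMatrix++;
      if (c < extMinC) extMinC = c;
      if (c > extMaxC) extMaxC = c;
      if (r < extMinR) extMinR = r;
      if (r > extMaxR) extMaxR = r;
      // keep the cached lumen-contact map current (contacts only added)
      if (!lumenContact.empty()) {
        if (On.kind == KIND_LUMEN) {
          for (int k = 0; k < 6; k++) {
            int w = ownerAt(c + DC[k], r + DR[k]);
            if (w != 0 && objs[w].kind == KIND_CELL && lumenContact[w] == 0)
              lumenContact[w] = n;
          }
        } else {
          for (int k = 0; k < 6; k++) {
            int w = ownerAt(c + DC[k], r + DR[k]);
            if (w != 0 && objs[w].kind == KIND_LUMEN && lumenContact[n] == 0)
              lumenContact[n] = w;
          }
        }
      }
    }
  }

  void recountAP(int id) {
    Obj &o = objs[id];
    int A = 0, P = 0;
    for (int r = 0; r < H; r++)
      for (int c = 0; c < W; c++)
        if (owner[idx(c, r)] == id) {
          A++;
          for (int k = 0; k < 6; k++)
            if (ownerAt(c + DC[k], r + DR[k]) != id) P++;
        }
    o.A = A; o.P = P;
  }

  // ------------------------------------------------------------ cycle phases
  void engulfPhase() {
    int c0 = std::max(0, extMinC - 1), c1 = std::min(W - 1, extMaxC + 1);
    int r0 = std::max(0, extMinR - 1), r1 = std::min(H - 1, extMaxR + 1);
    for (int r = r0; r <= r1; r++) {
      for (int c = c0; c <= c1; c++) {
        if (owner[idx(c, r)] != 0) continue;
        int cnt[6]; int ids[6]; int nids = 0;
        bool allOwned = true;
        for (int k = 0; k < 6; k++) {
          int nc = c + DC[k], nr = r + DR[k];
          if (!inField(nc, nr) || owner[idx(nc, nr)] == 0) { allOwned = false; break; }
          int w = owner[idx(nc, nr)];
          int j = -1;
          for (int t = 0; t < nids; t++) if (ids[t] == w) { j = t; break; }
          if (j < 0) { ids[nids] = w; cnt[nids] = 1; nids++; }
          else cnt[j]++;
        }
        if (!allOwned) continue;
        int best = ids[0], bestCnt = cnt[0];
        for (int t = 1; t < nids; t++) {
          if (cnt[t] > bestCnt || (cnt[t] == bestCnt && ids[t] < best)) {
            best = ids[t]; bestCnt = cnt[t];
          }
        }
        applyFlip(c, r, best);
      }
    }
  }

  void mergeLumens(int target, int source) {
    // collect and reassign source sites, then recount both
    double sx = 0, sy = 0; int ns = 0;
    for (int r = 0; r < H; r++)
      for (int c = 0; c < W; c++)
        if (owner[idx(c, r)] == source) {
          owner[idx(c, r)] = target;
          sx += X(idx(c, r)); sy += Y(idx(c, r)); ns++;
        }
    objs[target].TA += objs[source].TA;
    objs[source].alive = false;
    objs[source].A = 0; objs[source].P = 0;
    for (size_t i = 0; i < lumenContact.size(); i++)
      if (lumenContact[i] == source) lumenContact[i] = target;
    recountAP(target);
    if (ns > 0) pushEvent(cycle + 1, target, "lumen_merge", sx / ns, sy / ns);
  }

  void lumenGrowthPhase() {
    bool merged = false;
    for (int id = 1; id < (int)objs.size(); id++) {
      Obj &o = objs[id];
      if (!o.alive || o.kind != KIND_LUMEN) continue;
      const std::vector<int> &nb = lumNbCells[id];
      int nNb = (int)nb.size();
      if (nNb < 1) continue;
      double est = o.A;
      std::vector<double> strs;
      for (int c : nb) {
        est += objs[c].A;
        if (objs[c].dying) continue;   // dying cells do not resist expansion
        double str = (objs[c].TP > 0) ? objs[c].P / objs[c].TP - 1.0 : 0.0;
        strs.push_back(std::max(0.0, str));
      }
      // sum-form growth law: the rate scales with the estimated cyst mass
      // and the typical (median) distension of the surrounding living cells
      // brakes it; the median keeps single deformed cells from stalling the
      // whole lumen
      double medStr = 0.0;
      if (!strs.empty()) {
        std::sort(strs.begin(), strs.end());
        size_t m = strs.size() / 2;
        medStr = (strs.size() % 2) ? strs[m] : 0.5 * (strs[m - 1] + strs[m]);
      }
      double inc = par.lumenGrowthRate * (est + nNb) -
                   par.lgrSubtract * medStr;
      if (inc > 0) o.TA += inc;
    }
    // lumens brought into direct contact (e.g. after the cells separating
    // them are resorbed) merge; TJ-mediated merging happens in the TJ pass
    for (auto &pr : lumenAdjPairs) {
      if (objs[pr.first].alive && objs[pr.second].alive) {
        mergeLumens(std::min(pr.first, pr.second), std::max(pr.first, pr.second));
        merged = true;
      }
    }
    if (merged) survey();
  }

  void deathPhase() {
    int n = (int)objs.size();
    // advance cells already dying first; a cell that initiates death this
    // cycle starts shrinking the following cycle
    for (int id = 1; id < n; id++) {
      Obj &o = objs[id];
      if (o.alive && o.kind == KIND_CELL && o.dying)
        o.TA = std::max(0.0, o.TA - par.dyingShrinkRate);
    }
    for (int id = 1; id < n; id++) {
      Obj &o = objs[id];
      if (!o.alive || o.kind != KIND_CELL || o.dying) continue;
      double rr = unif_rand();
      double rate = (matE[id] > 0) ? par.deathRateEpi : par.deathRateLumen;
      if (rr < rate) {
        o.dying = true;
        o.deathStart = cycle + 1;
        double cx = 0, cy = 0;
        for (int s : siteList[id]) { cx += X(s); cy += Y(s); }
        pushEvent(cycle + 1, id, "death_start",
                  cx / std::max(1, (int)siteList[id].size()),
                  cy / std::max(1, (int)siteList[id].size()));
      }
    }
  }

  void cellUpdatePhase() {
    int n = (int)objs.size();
    for (int id = 1; id < n; id++) {
      Obj &o = objs[id];
      if (!o.alive || o.kind != KIND_CELL) continue;
      if (o.dying) {
        // apoptotic cells lose their perimeter target and round up: with
        // TP = 0 every boundary-shortening move is downhill, so resorption
        // is paced by the TA staircase (dying_shrink_rate per cycle) alone
        o.TP = 0.0;
        continue;
      }
      double M = matE[id] / 2.0, L = lumE[id] / 2.0;
      if (o.state == ST_STAB) {
        o.TA = par.stableTargetArea + par.stableAreaSlope * L;
      } else {
        double Wp;
        if (M <= 0.0 || L <= 0.0) {
          Wp = o.A;   // no wedge defined without both arcs; TA moves to wedgeArea
        } else {
          double denom = M * M - L * L;
          Wp = (denom > 0.0) ? o.A * M * M / denom
                             : std::numeric_limits<double>::infinity();
        }
        double ta = o.A + (par.wedgeArea - Wp);
        if (ta > par.wedgeArea) ta = par.wedgeArea;
        if (!(ta >= 1.0)) ta = 1.0;
        o.TA = ta;
      }
      o.TP = par.multiplier * par.K * 2.0 * std::sqrt(M_PI * o.A);
      if (o.state == ST_UNPOL) {
        if (!o.polarStarted) {
          if (matE[id] > 0) {
            o.polarCounter = (0.75 + 0.5 * unif_rand()) * par.polarDelay;
            o.polarStarted = true;
          }
        } else {
          o.polarCounter -= 1.0;
        }
        if (o.polarStarted && o.polarCounter <= 0.0) {
          o.state = ST_POL;
          o.shiftStarted = true;
          o.shiftCounter = (0.75 + 0.5 * unif_rand()) * par.shiftDelay;
          pushEvent(cycle + 1, id, "polarize", NA_REAL, NA_REAL);
        }
      } else if (o.state == ST_POL) {
        bool stab = false;
        // lumen-size trigger (LS)
        if (matE[id] > 0 && lumenContact[id] > 0) {
          if (objs[lumenContact[id]].A / 1000.0 > par.stableRatio) stab = true;
        }
        // timer trigger (TS)
        if (o.shiftStarted) {
          o.shiftCounter -= 1.0;
          if (o.shiftCounter <= 0.0) stab = true;
        }
        if (stab) {
          o.state = ST_STAB;
          pushEvent(cycle + 1, id, "stabilize", NA_REAL, NA_REAL);
        }
      }
    }
  }

  bool siteFromPoint(double x, double y, int &cOut, int &rOut) const {
    double rf = y / SQRT3_2;
    double cf = x - rf / 2.0;
    double xc = cf, zc = rf, yc = -xc - zc;
    double rx = std::round(xc), ry = std::round(yc), rz = std::round(zc);
    double ddx = std::fabs(rx - xc), ddy = std::fabs(ry - yc),
           ddz = std::fabs(rz - zc);
    if (ddx > ddy && ddx > ddz) rx = -ry - rz;
    else if (ddy > ddz) ry = -rx - rz;
    else rz = -rx - ry;
    cOut = (int)rx; rOut = (int)rz;
    return inField(cOut, rOut);
  }

  void lumenCreationPhase() {
    int n = (int)objs.size();
    for (int cid = 1; cid < n; cid++) {
      Obj &cell = objs[cid];
      if (!cell.alive || cell.kind != KIND_CELL || cell.dying) continue;
      if (cell.state != ST_POL || !cell.hasMidbody) continue;
      if (matE[cid] == 0 || lumE[cid] > 0) continue;
      int mc, mr;
      if (!siteFromPoint(cell.mbx, cell.mby, mc, mr)) continue;
      {
        int mown = owner[idx(mc, mr)];
        if (mown != 0 && objs[mown].kind == KIND_LUMEN) continue;  // no-op
      }
      // the nascent lumen opens at the apical patch near the midbody: take
      // the closest site to the midbody (radius <= 2, deterministic order)
      // that satisfies every constraint the invariants demand
      int c = -1, r = -1;
      for (int rad = 0; rad <= 2 && c < 0; rad++) {
        for (int dr = -rad; dr <= rad && c < 0; dr++) {
          for (int dc = -rad; dc <= rad && c < 0; dc++) {
            if ((std::abs(dc) + std::abs(dr) + std::abs(dc + dr)) / 2 != rad)
              continue;
            int cc = mc + dc, rr = mr + dr;
            if (!inField(cc, rr)) continue;
            int s = idx(cc, rr);
            int own = owner[s];
            if (own != 0 && objs[own].kind == KIND_LUMEN) continue;
            bool creatorNear = (own == cid);
            bool partner = false, nbMatrix = false, conflict = false;
            for (int k = 0; k < 6; k++) {
              int nc = cc + DC[k], nr = rr + DR[k];
              if (!inField(nc, nr)) { nbMatrix = true; break; }
              int w = owner[idx(nc, nr)];
              if (w == 0) { nbMatrix = true; break; }
              if (w == cid) creatorNear = true;
              if (objs[w].kind == KIND_CELL) {
                if (lumE[w] > 0 && !objs[w].dying) conflict = true;
                if (w != cid && objs[w].state == ST_POL && !objs[w].dying &&
                    lumE[w] == 0)
                  partner = true;
              }
            }
            if (nbMatrix || !creatorNear || !partner || conflict) continue;
            if (own != 0) {
              if (lumE[own] > 0 && !objs[own].dying) continue;
              if (objs[own].A <= 1 || connectivityViolation(cc, rr, own))
                continue;
            }
            c = cc; r = rr;
          }
        }
      }
      if (c < 0) continue;
      int s = idx(c, r);
      int own = owner[s];
      Obj lum;
      lum.kind = KIND_LUMEN; lum.state = 0; lum.dying = false; lum.alive = true;
      lum.A = 0; lum.TA = 1.0; lum.P = 0; lum.TP = 0.0;
      lum.cycleCounter = 0; lum.polarCounter = 0; lum.polarStarted = false;
      lum.shiftCounter = 0; lum.shiftStarted = false;
      lum.mbx = 0; lum.mby = 0; lum.hasMidbody = false; lum.deathStart = 0;
      objs.push_back(lum);
      int lid = (int)objs.size() - 1;
      matE.push_back(0); lumE.push_back(0); cellE.push_back(0);
      lumenContact.push_back(0);
      lumNbCells.push_back(std::vector<int>());
      siteList.push_back(std::vector<int>());
      applyFlip(c, r, lid);
      siteList[lid].push_back(s);
      // refresh cached contacts for adjacent cells
      for (int k = 0; k < 6; k++) {
        int w = ownerAt(c + DC[k], r + DR[k]);
        if (w > 0 && objs[w].kind == KIND_CELL) {
          lumE[w]++;
          lumenContact[w] = lid;
        }
      }
      pushEvent(cycle + 1, lid, "lumen_create", X(s), Y(s));
    }
  }

  // components of a site set (restricted adjacency); returns component index
  // per position, components sorted so that 0 is the largest
  int componentsOf(const std::vector<int> &sites, std::vector<int> &comp) {
    if ((int)stamp.size() != W * H) stamp.assign(W * H, 0);
    stampCtr++;
    int base = stampCtr;
    std::vector<int> pos(sites.size());
    for (size_t i = 0; i < sites.size(); i++) stamp[sites[i]] = base;
    // second stamp layer to store component id: use map from site -> comp
    comp.assign(sites.size(), -1);
    std::vector<int> compOf(W * H, -1);  // small W*H ok
    int nc = 0;
    std::vector<int> sizes;
    for (size_t i = 0; i < sites.size(); i++) {
      if (compOf[sites[i]] >= 0 || stamp[sites[i]] != base) continue;
      // BFS
      int cidx = nc++;
      sizes.push_back(0);
      bfsStack.clear();
      bfsStack.push_back(sites[i]);
      compOf[sites[i]] = cidx;
      while (!bfsStack.empty()) {
        int t = bfsStack.back(); bfsStack.pop_back();
        sizes[cidx]++;
        int tc = t % W, tr = t / W;
        for (int k = 0; k < 6; k++) {
          int ncol = tc + DC[k], nrow = tr + DR[k];
          if (!inField(ncol, nrow)) continue;
          int u = idx(ncol, nrow);
          if (stamp[u] == base && compOf[u] < 0) {
            compOf[u] = cidx;
            bfsStack.push_back(u);
          }
        }
      }
    }
    // largest component -> 0
    int best = 0;
    for (int i = 1; i < nc; i++)
      if (sizes[i] > sizes[best]) best = i;
    for (size_t i = 0; i < sites.size(); i++) {
      int cc = compOf[sites[i]];
      comp[i] = (cc == best) ? 0 : (cc < best ? cc + 1 : cc);
    }
    return nc;
  }

  // returns daughter id, or 0 if deferred
  int divideOne(int id) {
    std::vector<int> S = siteList[id];
    int A = (int)S.size();
    if (A < 2) return 0;
    double cx = 0, cy = 0;
    for (int s : S) { cx += X(s); cy += Y(s); }
    cx /= A; cy /= A;
    // division line direction
    int mode = par.divisionReg;
    bool oriented = (mode == 1 || mode == 3 ||
                     (mode == 2 && objs[id].state != ST_UNPOL));
    double dx, dy;
    if (!oriented) {
      double th = unif_rand() * 2.0 * M_PI;
      dx = std::cos(th); dy = std::sin(th);
    } else {
      int ell = (lumE[id] > 0 && lumenContact[id] > 0) ? lumenContact[id] : 0;
      bool ok = false;
      if (ell > 0 && !siteList[ell].empty()) {
        double lx = 0, ly = 0;
        for (int s : siteList[ell]) { lx += X(s); ly += Y(s); }
        lx /= siteList[ell].size(); ly /= siteList[ell].size();
        dx = lx - cx; dy = ly - cy;
        ok = std::hypot(dx, dy) > 1e-9;
      }
      if (!ok && objs[id].hasMidbody) {
        dx = objs[id].mbx - cx; dy = objs[id].mby - cy;
        ok = std::hypot(dx, dy) > 1e-9;
      }
      if (!ok) {
        double th = unif_rand() * 2.0 * M_PI;
        dx = std::cos(th); dy = std::sin(th);
      } else {
        double len = std::hypot(dx, dy);
        dx /= len; dy /= len;
      }
      if (mode == 3) { double t = dx; dx = -dy; dy = t; }   // rotate 90 deg
    }
    // signed distance to the division line; daughter takes the most-positive
    // half (median split: exact halving, odd remainder stays with the parent)
    std::vector<std::pair<double,int>> ds(A);
    for (int i = 0; i < A; i++) {
      int s = S[i];
      ds[i] = std::make_pair(dx * (Y(s) - cy) - dy * (X(s) - cx), s);
    }
    std::sort(ds.begin(), ds.end(), [](const std::pair<double,int> &a,
                                       const std::pair<double,int> &b) {
      if (a.first != b.first) return a.first > b.first;
      return a.second < b.second;
    });
    int nd = A / 2;
    std::vector<int> dSites, pSites;
    for (int i = 0; i < A; i++)
      (i < nd ? dSites : pSites).push_back(ds[i].second);
    // connectivity repair: stray fragments swap sides
    for (int it = 0; it < 4; it++) {
      std::vector<int> compD, compP;
      int ncd = dSites.empty() ? 0 : componentsOf(dSites, compD);
      int ncp = pSites.empty() ? 0 : componentsOf(pSites, compP);
      if (ncd <= 1 && ncp <= 1) break;
      std::vector<int> nD, nP;
      for (size_t i = 0; i < dSites.size(); i++)
        (compD[i] == 0 ? nD : nP).push_back(dSites[i]);
      for (size_t i = 0; i < pSites.size(); i++)
        (compP[i] == 0 ? nP : nD).push_back(pSites[i]);
      dSites.swap(nD); pSites.swap(nP);
    }
    {
      std::vector<int> compD, compP;
      if (dSites.empty() || pSites.empty()) return 0;
      if (componentsOf(dSites, compD) > 1) return 0;
      if (componentsOf(pSites, compP) > 1) return 0;
    }
    // build daughter
    Obj d = objs[id];
    d.dying = false;
    d.mbx = cx; d.mby = cy; d.hasMidbody = true;
    objs[id].mbx = cx; objs[id].mby = cy; objs[id].hasMidbody = true;
    objs.push_back(d);
    int did = (int)objs.size() - 1;
    matE.push_back(0); lumE.push_back(0); cellE.push_back(0);
    lumenContact.push_back(lumenContact[id]);   // daughter shares the contact
    lumNbCells.push_back(std::vector<int>());
    siteList.push_back(std::vector<int>());
    for (int s : dSites) owner[s] = did;
    siteList[id] = pSites;
    siteList[did] = dSites;
    // recount areas/perimeters of both halves
    for (int two = 0; two < 2; two++) {
      int oid = two ? did : id;
      Obj &oo = objs[oid];
      oo.A = (int)siteList[oid].size();
      int P = 0;
      for (int s : siteList[oid]) {
        int sc = s % W, sr = s / W;
        for (int k = 0; k < 6; k++)
          if (ownerAt(sc + DC[k], sr + DR[k]) != oid) P++;
      }
      oo.P = P;
      oo.TA = oo.A;
      oo.TP = par.multiplier * par.K * 2.0 * std::sqrt(M_PI * oo.A);
    }
    // counters
    if (!firstDivisionDone) {
      firstDivisionDone = true;
      double lo = (1.0 - par.clusterProb) * par.cellCycle;
      objs[id].cycleCounter = lo + unif_rand() * (par.cellCycle - lo);
      objs[did].cycleCounter = lo + unif_rand() * (par.cellCycle - lo);
    } else {
      objs[id].cycleCounter = (0.75 + 0.5 * unif_rand()) * par.cellCycle;
      objs[did].cycleCounter = (0.75 + 0.5 * unif_rand()) * par.cellCycle;
    }
    if (objs[id].polarStarted) {
      objs[did].polarCounter = (0.5 + unif_rand()) * par.polarDelay -
                               par.polarDelay + objs[id].polarCounter;
      objs[did].polarStarted = true;
    }
    pushEvent(cycle + 1, id, "divide", cx, cy);
    return did;
  }

  void divisionPhase() {
    int curCycle = cycle + 1;
    int nAtStart = (int)objs.size();
    std::vector<int> dividers;
    for (int id = 1; id < nAtStart; id++) {
      Obj &o = objs[id];
      if (!o.alive || o.kind != KIND_CELL || o.dying) continue;
      if (curCycle == 1) { o.cycleCounter = 1.0; continue; }
      if (o.A > par.doublingArea / 2.0) {
        if (o.state == ST_STAB) {
          double rr = unif_rand();
          if (rr < 1.0 - par.stableCycleDelay) o.cycleCounter -= 1.0;
        } else {
          o.cycleCounter -= 1.0;
        }
      }
      if (o.cycleCounter <= 0.0) dividers.push_back(id);
    }
    if (dividers.empty()) return;
    survey();
    for (int id : dividers) divideOne(id);
  }

  void pottsPhase() {
    long attempts = (long)std::llround(par.attemptsFactor * (double)nonMatrix);
    int c0 = std::max(0, extMinC - 2), c1 = std::min(W - 1, extMaxC + 2);
    int r0 = std::max(0, extMinR - 2), r1 = std::min(H - 1, extMaxR + 2);
    int bw = c1 - c0 + 1, bh = r1 - r0 + 1;
    if (bw <= 0 || bh <= 0) return;
    for (long t = 0; t < attempts; t++) {
      int c = c0 + std::min(bw - 1, (int)(unif_rand() * bw));
      int r = r0 + std::min(bh - 1, (int)(unif_rand() * bh));
      int k = std::min(5, (int)(unif_rand() * 6));
      int o = owner[idx(c, r)];
      int n = ownerAt(c + DC[k], r + DR[k]);
      if (n == o) continue;
      nAttempts++;
      double dG = deltaG(c, r, n, false);
      if (acceptMove(dG)) {
        applyFlip(c, r, n);
        nAccepted++;
      }
    }
  }

  // lumen id if site s is currently a TJ point (a cell site participating in
  // a TJ triangle), else 0
  int tjPointLumenLive(int c, int r) const {
    if (!inField(c, r)) return 0;
    int a = owner[idx(c, r)];
    if (a == 0 || objs[a].kind != KIND_CELL) return 0;
    for (int k = 0; k < 6; k++) {
      int k2 = (k + 1) % 6;
      int c1 = c + DC[k], r1 = r + DR[k];
      int c2 = c + DC[k2], r2 = r + DR[k2];
      if (!inField(c1, r1) || !inField(c2, r2)) continue;
      int w1 = owner[idx(c1, r1)], w2 = owner[idx(c2, r2)];
      if (isTJtriple(a, w1, w2)) {
        if (w1 != 0 && objs[w1].kind == KIND_LUMEN) return w1;
        if (w2 != 0 && objs[w2].kind == KIND_LUMEN) return w2;
      }
    }
    return 0;
  }

  bool tjConvertEligible(int c, int r, int lp) const {
    for (int k = 0; k < 6; k++) {
      int nc = c + DC[k], nr = r + DR[k];
      if (!inField(nc, nr)) return false;            // border counts as matrix
      int w = owner[idx(nc, nr)];
      if (w == 0) return false;                      // matrix neighbor
      if (objs[w].kind == KIND_LUMEN && w != lp) return false;
      if (objs[w].kind == KIND_CELL && objs[w].state == ST_UNPOL) return false;
    }
    return true;
  }

  void tjPhase() {
    // cached per-cell lumen contact for the single-lumen guard
    int n = (int)objs.size();
    std::vector<int> lc(n, 0);
    std::vector<int> tjList;
    for (int r = 0; r < H; r++) {
      for (int c = 0; c < W; c++) {
        int a = owner[idx(c, r)];
        if (a == 0 || objs[a].kind != KIND_CELL) continue;
        for (int k = 0; k < 6; k++) {
          int w = ownerAt(c + DC[k], r + DR[k]);
          if (w > 0 && objs[w].kind == KIND_LUMEN) {
            if (lc[a] == 0) lc[a] = w;
            else if (lc[a] != w) lc[a] = -1;
          }
        }
        if (tjPointLumenLive(c, r) > 0) tjList.push_back(idx(c, r));
      }
    }
    auto contactsOk = [&](int c, int r, int l1, int l2) {
      for (int k = 0; k < 6; k++) {
        int w = ownerAt(c + DC[k], r + DR[k]);
        if (w > 0 && objs[w].kind == KIND_CELL && !objs[w].dying) {
          int cc = lc[w];
          if (cc != 0 && cc != l1 && cc != l2) return false;
          if (cc == -1) return false;
        }
      }
      return true;
    };
    // pass 1: adjacent TJs of different lumens trigger reorganization + merge
    for (int p : tjList) {
      int pc = p % W, pr = p / W;
      int lp = tjPointLumenLive(pc, pr);
      if (lp == 0) continue;
      int cp = owner[p];
      for (int k = 0; k < 6; k++) {
        int qc = pc + DC[k], qr = pr + DR[k];
        int lq = tjPointLumenLive(qc, qr);
        if (lq == 0 || lq == lp || !objs[lq].alive || !objs[lp].alive) continue;
        int cq = owner[idx(qc, qr)];
        if (cq == cp) continue;
        if (!tjConvertEligible(pc, pr, lp) || !tjConvertEligible(qc, qr, lq))
          continue;
        if (!contactsOk(pc, pr, lp, lq) || !contactsOk(qc, qr, lp, lq))
          continue;
        if (objs[cp].A <= 1 || connectivityViolation(pc, pr, cp)) continue;
        if (objs[cq].A <= 1 || connectivityViolation(qc, qr, cq)) continue;
        applyFlip(pc, pr, lp);
        applyFlip(qc, qr, lq);
        int tgt = std::min(lp, lq), src = std::max(lp, lq);
        mergeLumens(tgt, src);
        for (int i = 1; i < n; i++) if (lc[i] == src) lc[i] = tgt;
        for (int k2 = 0; k2 < 6; k2++) {
          int w = ownerAt(pc + DC[k2], pr + DR[k2]);
          if (w > 0 && w < n && objs[w].kind == KIND_CELL && lc[w] == 0) lc[w] = tgt;
          w = ownerAt(qc + DC[k2], qr + DR[k2]);
          if (w > 0 && w < n && objs[w].kind == KIND_CELL && lc[w] == 0) lc[w] = tgt;
        }
        break;
      }
    }
    // pass 2: TJ points may convert to lumen (expansion), energy-gated
    for (int p : tjList) {
      int pc = p % W, pr = p / W;
      int lp = tjPointLumenLive(pc, pr);
      if (lp == 0 || !objs[lp].alive) continue;
      int cp = owner[p];
      if (!tjConvertEligible(pc, pr, lp)) continue;
      // a neighboring point in a different cell that is not itself a TJ
      // becomes the new TJ after conversion; the partner cell must already
      // hold apical surface on this lumen (junctions slide along the ring,
      // they do not insert apical membrane into a contact-free cell)
      bool hasNew = false;
      for (int k = 0; k < 6; k++) {
        int qc = pc + DC[k], qr = pr + DR[k];
        if (!inField(qc, qr)) continue;
        int w = owner[idx(qc, qr)];
        if (w > 0 && objs[w].kind == KIND_CELL && w != cp &&
            lc[w] == lp && tjPointLumenLive(qc, qr) == 0) {
          hasNew = true;
          break;
        }
      }
      if (!hasNew) continue;
      if (!contactsOk(pc, pr, lp, lp)) continue;
      if (objs[cp].A <= 1 || connectivityViolation(pc, pr, cp)) continue;
      double dG = deltaG(pc, pr, lp, true);
      if (acceptMove(dG)) {
        applyFlip(pc, pr, lp);
        for (int k = 0; k < 6; k++) {
          int w = ownerAt(pc + DC[k], pr + DR[k]);
          if (w > 0 && w < n && objs[w].kind == KIND_CELL && lc[w] == 0)
            lc[w] = lp;
        }
      }
    }
  }

  void auditState() {
    int n = (int)objs.size();
    std::vector<int> Ar(n, 0), Pr(n, 0);
    long tot = 0;
    for (int r = 0; r < H; r++) {
      for (int c = 0; c < W; c++) {
        int a = owner[idx(c, r)];
        if (a == 0) continue;
        if (a < 0 || a >= n || !objs[a].alive)
          stop("audit: site owned by invalid object %d at (%d,%d)", a, c, r);
        tot++;
        Ar[a]++;
        for (int k = 0; k < 6; k++) {
          int w = ownerAt(c + DC[k], r + DR[k]);
          if (w != a) Pr[a]++;
          if (objs[a].kind == KIND_LUMEN && w == 0)
            stop("audit: lumen %d adjacent to matrix at (%d,%d)", a, c, r);
        }
      }
    }
    for (int id = 1; id < n; id++) {
      Obj &o = objs[id];
      if (!o.alive) {
        if (Ar[id] != 0) stop("audit: dead object %d still owns sites", id);
        continue;
      }
      if (Ar[id] != o.A)
        stop("audit: area bookkeeping mismatch for %d (%d vs %d)", id, o.A, Ar[id]);
      if (Pr[id] != o.P)
        stop("audit: perimeter bookkeeping mismatch for %d (%d vs %d)", id, o.P, Pr[id]);
      if (Ar[id] == 0) stop("audit: alive object %d has no sites", id);
    }
    // connectivity + single-lumen contact
    survey();
    for (int id = 1; id < n; id++) {
      if (!objs[id].alive) continue;
      const std::vector<int> &S = siteList[id];
      std::vector<int> comp;
      if (componentsOf(S, comp) > 1)
        stop("audit: object %d disconnected", id);
      if (objs[id].kind == KIND_CELL && !objs[id].dying &&
          lumenContact[id] == -1)
        stop("audit: cell %d contacts multiple lumens", id);
    }
    if (tot != nonMatrix) stop("audit: non-matrix site count mismatch");
  }

  void runCycle(int auditLevel) {
    survey();
    engulfPhase();
    survey();
    lumenGrowthPhase();
    deathPhase();
    cellUpdatePhase();
    lumenCreationPhase();
    divisionPhase();
    pottsPhase();
    tjPhase();
    cycle += 1;
    if (auditLevel >= 2) auditState();
  }
};

// ----------------------------------------------------------- R serialization

static Engine engineFromState(List state, List params) {
  Engine e;
  e.par = parseParams(params);
  e.W = as<int>(state["width"]);
  e.H = as<int>(state["height"]);
  IntegerMatrix om = as<IntegerMatrix>(state["owner"]);
  if (om.nrow() != e.W || om.ncol() != e.H)
    stop("owner matrix must be width x height");
  e.owner.assign(e.W * e.H, 0);
  for (int r = 0; r < e.H; r++)
    for (int c = 0; c < e.W; c++) e.owner[e.idx(c, r)] = om(c, r);
  e.cycle = as<int>(state["cycle"]);
  e.firstDivisionDone = as<bool>(state["first_division_done"]);
  DataFrame od = as<DataFrame>(state["objects"]);
  IntegerVector kind = od["kind"], st = od["state"], A = od["A"], P = od["P"],
                deathStart = od["death_start"];
  LogicalVector dying = od["dying"], alive = od["alive"],
                polarStarted = od["polar_started"],
                shiftStarted = od["shift_started"], hasMb = od["has_midbody"];
  NumericVector TA = od["TA"], TP = od["TP"], cc = od["cycle_counter"],
                pc = od["polar_counter"], sc = od["shift_counter"],
                mbx = od["mb_x"], mby = od["mb_y"];
  int n = od.nrows();
  e.objs.resize(n + 1);
  for (int i = 0; i < n; i++) {
    Obj &o = e.objs[i + 1];
    o.kind = kind[i]; o.state = st[i]; o.dying = dying[i]; o.alive = alive[i];
    o.A = A[i]; o.TA = TA[i]; o.P = P[i]; o.TP = TP[i];
    o.cycleCounter = cc[i]; o.polarCounter = pc[i];
    o.polarStarted = polarStarted[i];
    o.shiftCounter = sc[i]; o.shiftStarted = shiftStarted[i];
    o.mbx = mbx[i]; o.mby = mby[i]; o.hasMidbody = hasMb[i];
    o.deathStart = deathStart[i];
  }
  // recompute derived counters
  e.nonMatrix = 0;
  e.extMinC = e.W; e.extMaxC = -1; e.extMinR = e.H; e.extMaxR = -1;
  for (int r = 0; r < e.H; r++)
    for (int c = 0; c < e.W; c++)
      if (e.owner[e.idx(c, r)] != 0) {
        e.nonMatrix++;
        if (c < e.extMinC) e.extMinC = c;
        if (c > e.extMaxC) e.extMaxC = c;
        if (r < e.extMinR) e.extMinR = r;
        if (r > e.extMaxR) e.extMaxR = r;
      }
  e.survey();   // populate site lists, boundary counts and the contact cache
  return e;
}

static List stateToList(const Engine &e) {
  IntegerMatrix om(e.W, e.H);
  for (int r = 0; r < e.H; r++)
    for (int c = 0; c < e.W; c++) om(c, r) = e.owner[e.idx(c, r)];
  int n = (int)e.objs.size() - 1;
  IntegerVector id(n), kind(n), st(n), A(n), P(n), deathStart(n);
  LogicalVector dying(n), alive(n), polarStarted(n), shiftStarted(n), hasMb(n);
  NumericVector TA(n), TP(n), cc(n), pc(n), sc(n), mbx(n), mby(n);
  for (int i = 0; i < n; i++) {
    const Obj &o = e.objs[i + 1];
    id[i] = i + 1; kind[i] = o.kind; st[i] = o.state;
    dying[i] = o.dying; alive[i] = o.alive;
    A[i] = o.A; TA[i] = o.TA; P[i] = o.P; TP[i] = o.TP;
    cc[i] = o.cycleCounter; pc[i] = o.polarCounter;
    polarStarted[i] = o.polarStarted;
    sc[i] = o.shiftCounter; shiftStarted[i] = o.shiftStarted;
    mbx[i] = o.mbx; mby[i] = o.mby; hasMb[i] = o.hasMidbody;
    deathStart[i] = o.deathStart;
  }
  DataFrame od = DataFrame::create(
      _["id"] = id, _["kind"] = kind, _["state"] = st, _["dying"] = dying,
      _["alive"] = alive, _["A"] = A, _["TA"] = TA, _["P"] = P, _["TP"] = TP,
      _["cycle_counter"] = cc, _["polar_counter"] = pc,
      _["polar_started"] = polarStarted, _["shift_counter"] = sc,
      _["shift_started"] = shiftStarted, _["mb_x"] = mbx, _["mb_y"] = mby,
      _["has_midbody"] = hasMb, _["death_start"] = deathStart);
  return List::create(
      _["width"] = e.W, _["height"] = e.H, _["owner"] = om,
      _["objects"] = od, _["cycle"] = e.cycle,
      _["first_division_done"] = e.firstDivisionDone);
}

static DataFrame eventsToDf(const Engine &e) {
  return DataFrame::create(
      _["cycle"] = wrap(e.evCycle), _["id"] = wrap(e.evId),
      _["event"] = wrap(e.evName), _["x"] = wrap(e.evX),
      _["y"] = wrap(e.evY), _["stringsAsFactors"] = false);
}

// ------------------------------------------------------------------ exports

// [[Rcpp::export]]
List engine_run(List state, List params, int n_cycles, int stride,
                int audit_level) {
  Engine e = engineFromState(state, params);
  List snapshots;
  std::vector<int> snapCycles;
  for (int i = 0; i < n_cycles; i++) {
    e.runCycle(audit_level);
    if (stride > 0 && e.cycle % stride == 0) {
      snapshots.push_back(stateToList(e));
      snapCycles.push_back(e.cycle);
    }
  }
  if (audit_level >= 1) e.auditState();
  return List::create(
      _["final"] = stateToList(e), _["snapshots"] = snapshots,
      _["snapshot_cycles"] = wrap(snapCycles), _["events"] = eventsToDf(e),
      _["attempts"] = (double)e.nAttempts, _["accepted"] = (double)e.nAccepted);
}

// [[Rcpp::export]]
double engine_delta_g(List state, List params, int col, int row,
                      int candidate_id, bool bypass_tj) {
  Engine e = engineFromState(state, params);
  if (!e.inField(col, row)) stop("site out of field");
  int o = e.owner[e.idx(col, row)];
  if (candidate_id == o) stop("candidate equals current occupant");
  // candidate must occupy a neighboring site (local moves only)
  bool adj = false;
  for (int k = 0; k < 6; k++)
    if (e.ownerAt(col + DC[k], row + DR[k]) == candidate_id) { adj = true; break; }
  if (!adj) stop("candidate object is not adjacent to the site");
  return e.deltaG(col, row, candidate_id, bypass_tj);
}

// [[Rcpp::export]]
List engine_potts_step(List state, List params, int n_attempts) {
  Engine e = engineFromState(state, params);
  double saveFactor = e.par.attemptsFactor;
  (void)saveFactor;
  // run exactly n_attempts proposals
  long before = e.nAccepted;
  e.par.attemptsFactor = 0;  // unused below
  {
    int c0 = std::max(0, e.extMinC - 2), c1 = std::min(e.W - 1, e.extMaxC + 2);
    int r0 = std::max(0, e.extMinR - 2), r1 = std::min(e.H - 1, e.extMaxR + 2);
    int bw = c1 - c0 + 1, bh = r1 - r0 + 1;
    for (int t = 0; t < n_attempts && bw > 0 && bh > 0; t++) {
      int c = c0 + std::min(bw - 1, (int)(unif_rand() * bw));
      int r = r0 + std::min(bh - 1, (int)(unif_rand() * bh));
      int k = std::min(5, (int)(unif_rand() * 6));
      int o = e.owner[e.idx(c, r)];
      int n = e.ownerAt(c + DC[k], r + DR[k]);
      if (n == o) continue;
      e.nAttempts++;
      double dG = e.deltaG(c, r, n, false);
      if (e.acceptMove(dG)) { e.applyFlip(c, r, n); e.nAccepted++; }
    }
  }
  return List::create(_["state"] = stateToList(e),
                      _["proposals"] = (double)e.nAttempts,
                      _["accepted"] = (double)(e.nAccepted - before));
}

// [[Rcpp::export]]
bool engine_connectivity_violation(List state, List params, int col, int row) {
  Engine e = engineFromState(state, params);
  if (!e.inField(col, row)) stop("site out of field");
  int o = e.owner[e.idx(col, row)];
  if (o == 0) stop("site belongs to matrix");
  return e.connectivityViolation(col, row, o);
}

// [[Rcpp::export]]
List engine_divide(List state, List params, int id) {
  Engine e = engineFromState(state, params);
  if (id < 1 || id >= (int)e.objs.size() || !e.objs[id].alive ||
      e.objs[id].kind != KIND_CELL)
    stop("id is not a living cell");
  e.survey();
  int did = e.divideOne(id);
  return List::create(_["state"] = stateToList(e), _["daughter"] = did,
                      _["events"] = eventsToDf(e));
}

// [[Rcpp::export]]
NumericVector engine_division_axis(List state, List params, int id) {
  Engine e = engineFromState(state, params);
  if (id < 1 || id >= (int)e.objs.size() || !e.objs[id].alive)
    stop("id is not a living object");
  e.survey();
  const std::vector<int> &S = e.siteList[id];
  double cx = 0, cy = 0;
  for (int s : S) { cx += e.X(s); cy += e.Y(s); }
  cx /= S.size(); cy /= S.size();
  int mode = e.par.divisionReg;
  bool oriented = (mode == 1 || mode == 3 ||
                   (mode == 2 && e.objs[id].state != ST_UNPOL));
  double dx, dy;
  if (!oriented) {
    double th = unif_rand() * 2.0 * M_PI;
    dx = std::cos(th); dy = std::sin(th);
  } else {
    int ell = (e.lumE[id] > 0 && e.lumenContact[id] > 0) ? e.lumenContact[id] : 0;
    bool ok = false;
    dx = dy = 0;
    if (ell > 0 && !e.siteList[ell].empty()) {
      double lx = 0, ly = 0;
      for (int s : e.siteList[ell]) { lx += e.X(s); ly += e.Y(s); }
      lx /= e.siteList[ell].size(); ly /= e.siteList[ell].size();
      dx = lx - cx; dy = ly - cy;
      ok = std::hypot(dx, dy) > 1e-9;
    }
    if (!ok && e.objs[id].hasMidbody) {
      dx = e.objs[id].mbx - cx; dy = e.objs[id].mby - cy;
      ok = std::hypot(dx, dy) > 1e-9;
    }
    if (!ok) {
      double th = unif_rand() * 2.0 * M_PI;
      dx = std::cos(th); dy = std::sin(th);
    } else {
      double len = std::hypot(dx, dy);
      dx /= len; dy /= len;
    }
    if (mode == 3) { double t = dx; dx = -dy; dy = t; }
  }
  return NumericVector::create(dx, dy);
}

// [[Rcpp::export]]
List engine_engulf(List state, List params) {
  Engine e = engineFromState(state, params);
  e.survey();
  e.engulfPhase();
  return List::create(_["state"] = stateToList(e));
}

// [[Rcpp::export]]
DataFrame engine_tj_triples(List state, List params) {
  Engine e = engineFromState(state, params);
  std::vector<int> ac, ar, bc, br, lc_, lr, cellA, cellB, lum;
  for (int r = 0; r < e.H; r++) {
    for (int c = 0; c < e.W; c++) {
      int s0 = e.idx(c, r);
      for (int k = 0; k < 6; k++) {
        int k2 = (k + 1) % 6;
        int c1 = c + DC[k], r1 = r + DR[k];
        int c2 = c + DC[k2], r2 = r + DR[k2];
        if (!e.inField(c1, r1) || !e.inField(c2, r2)) continue;
        int s1 = e.idx(c1, r1), s2 = e.idx(c2, r2);
        if (s0 > s1 || s0 > s2) continue;   // each triangle listed once
        int w0 = e.owner[s0], w1 = e.owner[s1], w2 = e.owner[s2];
        if (!e.isTJtriple(w0, w1, w2)) continue;
        int sl = -1, sa = -1, sb = -1;
        int ss[3] = {s0, s1, s2};
        for (int i = 0; i < 3; i++) {
          int w = e.owner[ss[i]];
          if (e.objs[w].kind == KIND_LUMEN) sl = ss[i];
          else if (sa < 0) sa = ss[i];
          else sb = ss[i];
        }
        ac.push_back(sa % e.W); ar.push_back(sa / e.W);
        bc.push_back(sb % e.W); br.push_back(sb / e.W);
        lc_.push_back(sl % e.W); lr.push_back(sl / e.W);
        cellA.push_back(e.owner[sa]); cellB.push_back(e.owner[sb]);
        lum.push_back(e.owner[sl]);
      }
    }
  }
  return DataFrame::create(
      _["a_col"] = wrap(ac), _["a_row"] = wrap(ar), _["b_col"] = wrap(bc),
      _["b_row"] = wrap(br), _["lumen_col"] = wrap(lc_),
      _["lumen_row"] = wrap(lr), _["cell_a"] = wrap(cellA),
      _["cell_b"] = wrap(cellB), _["lumen"] = wrap(lum));
}

// [[Rcpp::export]]
bool engine_tj_local_change(List state, List params, int col, int row,
                            int candidate_id) {
  Engine e = engineFromState(state, params);
  if (!e.inField(col, row)) stop("site out of field");
  int o = e.owner[e.idx(col, row)];
  return e.tjTriCountAt(col, row, o) != e.tjTriCountAt(col, row, candidate_id);
}

// [[Rcpp::export]]
bool engine_audit(List state, List params) {
  Engine e = engineFromState(state, params);
  e.auditState();
  return true;
}

// [[Rcpp::export]]
List engine_merge_lumens(List state, List params, int a, int b) {
  Engine e = engineFromState(state, params);
  if (a < 1 || b < 1 || a >= (int)e.objs.size() || b >= (int)e.objs.size() ||
      !e.objs[a].alive || !e.objs[b].alive ||
      e.objs[a].kind != KIND_LUMEN || e.objs[b].kind != KIND_LUMEN)
    stop("both ids must be living lumens");
  // adjacency required
  bool adj = false;
  for (int r = 0; r < e.H && !adj; r++)
    for (int c = 0; c < e.W && !adj; c++)
      if (e.owner[e.idx(c, r)] == a)
        for (int k = 0; k < 6; k++)
          if (e.ownerAt(c + DC[k], r + DR[k]) == b) { adj = true; break; }
  if (!adj) stop("lumens %d and %d are not adjacent", a, b);
  e.mergeLumens(std::min(a, b), std::max(a, b));
  return List::create(_["state"] = stateToList(e), _["kept"] = std::min(a, b));
}
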