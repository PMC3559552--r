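// Lattice agent-based model of human endotoxemia with circadian control.
//
// Molecules are discrete agents on unitless rectangular grids: one plasma grid
// (which embeds an 11x11 brain region) and one 40x30 grid per leukocyte (which
// embeds an 11x11 nucleus region). Agents perform Moore-neighbourhood random
// walks with short-range attraction between interactive pairs, collide to fire
// activation/complexation/annihilation rules, and trigger per-residency
// Bernoulli production draws in the nucleus and brain. Two time scales apply:
// the life-scale S_l (production/degradation, ticks per hour) and the
// time-scale T_sc (wall-clock mapping). Per-tick life-process probabilities
// are scaled by S_l/T_sc so hourly rates are invariant to the time-scale.
//
// All randomness is drawn from R's RNG, so set.seed() on the R side makes
// every simulation bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

enum Sp {
  S_LPS = 0, S_TLR4, S_LPSR, S_IKK, S_NIKB, S_NFKB, S_IKB,
  S_P, S_A, S_E, S_F, S_GR, S_FR, S_M, NSP
};

enum Cm { C_PLASMA = 0, C_BRAIN = 1, C_CYTO = 2, C_NUC = 3 };

// event log rows (fixed order, mirrored in R/simulate.R)
enum Ev {
  E_DEFAULT_PROD = 0, E_DEGRADE, E_IMPORT_ATTEMPT, E_IMPORT,
  E_LPS_ATTEMPT, E_LPS_IMPORT, E_RELEASE,
  E_IKK_ACT, E_NFKB_FREED, E_COMPLEX, E_FR_FORMED, E_ANNIHILATION,
  E_ENTRY_NFKB, E_ENTRY_P, E_ENTRY_A, E_ENTRY_FR, E_ENTRY_M, E_ENTRY_IKB,
  E_BRAIN_ENTRY_F, E_BRAIN_ENTRY_P,
  E_PROD_KP, E_PROD_KI, E_PROD_PT, E_PROD_AE, E_PROD_FA, E_PROD_FI,
  E_PROD_MP, E_PROD_FM, E_PROD_PF,
  E_CIRC_F, E_CIRC_M, E_CONSUMED_E, NEV
};

static const int DX[8] = { 0, 1, 1, 1, 0, -1, -1, -1 };
static const int DY[8] = { -1, -1, 0, 1, 1, 1, 0, -1 };

static inline int ri(int n) { // uniform integer in [0, n)
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

struct Mol {
  int8_t sp;
  int8_t comp;
  int16_t cell;   // -1 for plasma/brain
  int16_t x, y;
  int8_t dir;
  int8_t steps;
  int8_t wait;
  bool active;    // import status; for IKK: kinase activated
  bool immobile;  // membrane-bound TLR4
  bool alive;
  int16_t lastTried; // refractory import target: cell id, -2 brain, -1 none
  int32_t last;   // tick of last non-movement event (creation, interaction, ...)
};

struct World {
  // geometry
  int PW, PH, CW, CH, nucSide, nucX0, nucY0, brainX0, brainY0, nCells;
  int CA;                      // cell grid area
  // clock
  int Sl, Tsc;
  double startHour;
  // parameters
  double Rprod, importProb;
  double kp, ki, fi, fa, fm, mp, pf, pt, ae;
  int theta, cellAttractRadius, waitMax, persistMax, cfm;
  double fWinStart, fWinPeak, mWinStart, mWinPeak;
  std::vector<double> lifeTicks;   // per species, in ticks (hours * Tsc)
  std::vector<int> initCell;       // per species
  int plasmaInitP, plasmaInitA;
  std::vector<char> ruleOn;        // indexed by rule id, 0..21
  bool circadian;

  // state
  std::vector<Mol> mol;
  std::vector<int> freeList;
  std::vector<std::vector<int>> occ;      // per global position: molecule idx
  std::vector<int> cellAt;                // plasma pos -> cell id or -1
  std::vector<int> cellPos;               // cell id -> plasma pos
  std::vector<int> attrCell;              // plasma pos -> plasma pos of nearby cell, or -1
  std::vector<int> tlr4At;                // nCells*CA: molecule idx of TLR4 at pos, or -1
  std::vector<int> boundaryPos;           // cell-grid positions on the ring
  std::vector<long long> cnt;             // nCells*NSP intracellular counts
  std::vector<long long> nucCnt;          // nCells*NSP nucleus counts
  long long brainCnt[NSP];
  long long gCnt[NSP];
  std::vector<int> activeIKK;             // per cell: activated kinases
  std::vector<int> energyAvail;           // per cell: usable E (excl. pending deletions)
  std::vector<int> pendingE;              // per cell: consumed E awaiting removal
  std::vector<int> inhibitE;              // per cell: hour in which default E prod is off
  int tick, curHour;

  std::vector<long long> ev;              // NEV * hours
  int evHours;

  int plasmaPos(int x, int y) const { return y * PW + x; }
  int cellGridPos(int c, int x, int y) const { return PW * PH + c * CA + y * CW + x; }
  int gpos(const Mol& m) const {
    return (m.comp <= C_BRAIN) ? plasmaPos(m.x, m.y) : cellGridPos(m.cell, m.x, m.y);
  }
  bool inBrain(int x, int y) const {
    return x >= brainX0 && x < brainX0 + nucSide && y >= brainY0 && y < brainY0 + nucSide;
  }
  bool inNucleus(int x, int y) const {
    return x >= nucX0 && x < nucX0 + nucSide && y >= nucY0 && y < nucY0 + nucSide;
  }
  bool onCellBoundary(int x, int y) const {
    return x == 0 || x == CW - 1 || y == 0 || y == CH - 1;
  }

  void logEv(int e) {
    int h = curHour;
    if (h >= evHours) h = evHours - 1;
    if (h < 0) h = 0;
    ev[(size_t)e * evHours + h]++;
  }

  void countsAdd(const Mol& m, int d) {
    gCnt[m.sp] += d;
    if (m.comp == C_BRAIN) brainCnt[m.sp] += d;
    if (m.comp >= C_CYTO) {
      cnt[(size_t)m.cell * NSP + m.sp] += d;
      if (m.comp == C_NUC) nucCnt[(size_t)m.cell * NSP + m.sp] += d;
      if (m.sp == S_E) energyAvail[m.cell] += d;
      if (m.sp == S_IKK && m.active) activeIKK[m.cell] += d;
    }
  }

  void occInsert(int i) { occ[gpos(mol[i])].push_back(i); }
  void occRemove(int i) {
    std::vector<int>& v = occ[gpos(mol[i])];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); return; }
  }

  int addMol(int sp, int comp, int cell, int x, int y, bool active, int32_t last,
             bool immobile = false) {
    int i;
    if (!freeList.empty()) { i = freeList.back(); freeList.pop_back(); }
    else { mol.push_back(Mol()); i = (int)mol.size() - 1; }
    Mol& m = mol[i];
    m.sp = (int8_t)sp; m.comp = (int8_t)comp; m.cell = (int16_t)cell;
    m.x = (int16_t)x; m.y = (int16_t)y;
    m.dir = (int8_t)ri(8); m.steps = (int8_t)(1 + ri(persistMax));
    m.wait = (int8_t)ri(waitMax + 1);
    m.active = active; m.immobile = immobile; m.alive = true; m.last = last;
    m.lastTried = -1;
    occInsert(i);
    countsAdd(m, +1);
    if (sp == S_TLR4 && comp == C_CYTO && immobile)
      tlr4At[(size_t)cell * CA + (y * CW + x)] = i;
    return i;
  }

  void removeMol(int i) {
    Mol& m = mol[i];
    if (!m.alive) return;
    occRemove(i);
    countsAdd(m, -1);
    if (m.sp == S_TLR4 && m.immobile) {
      size_t k = (size_t)m.cell * CA + (m.y * CW + m.x);
      if (tlr4At[k] == i) tlr4At[k] = -1;
    }
    m.alive = false;
    freeList.push_back(i);
  }

  // mutate position/compartment/species with full bookkeeping
  void relocate(int i, int sp, int comp, int cell, int x, int y) {
    Mol& m = mol[i];
    occRemove(i);
    countsAdd(m, -1);
    m.sp = (int8_t)sp; m.comp = (int8_t)comp; m.cell = (int16_t)cell;
    m.x = (int16_t)x; m.y = (int16_t)y;
    countsAdd(m, +1);
    occInsert(i);
  }

  void movePos(int i, int x, int y) {
    Mol& m = mol[i];
    occRemove(i);
    m.x = (int16_t)x; m.y = (int16_t)y;
    occInsert(i);
  }

  int randCytoPos(int c, int& ox, int& oy) {
    for (int t = 0; t < 200; ++t) {
      int x = ri(CW), y = ri(CH);
      if (!inNucleus(x, y)) { ox = x; oy = y; return 1; }
    }
    ox = 0; oy = 0; return 1;
  }

  int randBrainPos(int& ox, int& oy) {
    ox = brainX0 + ri(nucSide); oy = brainY0 + ri(nucSide); return 1;
  }

  int freeBoundaryPos(int c, int& ox, int& oy) {
    int nb = (int)boundaryPos.size();
    for (int t = 0; t < 60; ++t) {
      int p = boundaryPos[ri(nb)];
      if (tlr4At[(size_t)c * CA + p] < 0) { ox = p % CW; oy = p / CW; return 1; }
    }
    for (int k = 0; k < nb; ++k) {  // fall back to a scan
      int p = boundaryPos[k];
      if (tlr4At[(size_t)c * CA + p] < 0) { ox = p % CW; oy = p / CW; return 1; }
    }
    return 0;
  }

  bool spAllowed(int sp, int comp) const {
    switch (sp) {
      case S_LPS:  return comp == C_PLASMA;
      case S_TLR4: case S_LPSR: case S_IKK: case S_NIKB: case S_E: case S_GR:
        return comp == C_CYTO;
      case S_NFKB: case S_IKB: case S_FR:
        return comp == C_CYTO || comp == C_NUC;
      case S_P: return true;
      case S_A: case S_M: return comp != C_BRAIN;
      case S_F: return comp != C_NUC;
    }
    return false;
  }

  bool nucleusEligible(const Mol& m) const {
    switch (m.sp) {
      case S_NFKB: case S_IKB: case S_FR: return true;
      case S_P: case S_A: case S_M: return m.active;
      default: return false;
    }
  }

  void consumeE(int c) {
    if (energyAvail[c] <= 0) return;
    energyAvail[c]--;
    pendingE[c]++;
    inhibitE[c] = curHour;
    logEv(E_CONSUMED_E);
  }

  // --- production draws -----------------------------------------------------

  void spawnInCyto(int sp, int c) {
    int x, y;
    if (sp == S_TLR4) {
      if (!freeBoundaryPos(c, x, y)) return;
      addMol(sp, C_CYTO, c, x, y, false, tick, true);
    } else {
      randCytoPos(c, x, y);
      addMol(sp, C_CYTO, c, x, y, false, tick);
    }
  }

  void spawnFInBrain();  // forward (recursive through fm draw)

  void spawnMFromBrain() {
    // melatonin produced by brain activity circulates immediately: it is
    // placed at a brain-region lattice point with plasma compartment status
    int x, y; randBrainPos(x, y);
    addMol(S_M, C_PLASMA, -1, x, y, false, tick);
  }

  void brainEntryF() {
    logEv(E_BRAIN_ENTRY_F);
    bool blocked = ruleOn[16] && brainCnt[S_P] > 2 * brainCnt[S_F];
    if (ruleOn[13] && !blocked && unif_rand() < fm) {
      spawnMFromBrain();
      logEv(E_PROD_FM);
    }
  }

  void brainEntryP() {
    logEv(E_BRAIN_ENTRY_P);
    if (ruleOn[15] && unif_rand() < pf) {
      spawnFInBrain();
      logEv(E_PROD_PF);
    }
  }

  void nucleusEntry(int i) {
    Mol& m = mol[i];
    int c = m.cell;
    bool energy = energyAvail[c] > 0;
    switch (m.sp) {
      case S_NFKB: {
        logEv(E_ENTRY_NFKB);
        bool suppressed = ruleOn[11] &&
          nucCnt[(size_t)c * NSP + S_NFKB] < nucCnt[(size_t)c * NSP + S_FR];
        if (ruleOn[2] && !suppressed) {
          if (energyAvail[c] > 0 && unif_rand() < kp) {
            spawnInCyto(S_P, c); consumeE(c); logEv(E_PROD_KP);
          }
          if (energyAvail[c] > 0 && unif_rand() < ki) {
            spawnInCyto(S_IKB, c); consumeE(c); logEv(E_PROD_KI);
          }
        }
        break;
      }
      case S_P:
        logEv(E_ENTRY_P);
        if (ruleOn[7] && energy && unif_rand() < pt) {
          spawnInCyto(S_TLR4, c); consumeE(c); logEv(E_PROD_PT);
        }
        break;
      case S_A:
        logEv(E_ENTRY_A);
        // producing E replenishes energy; it costs none and does not inhibit
        // the default E production (otherwise rule 8 would be a net no-op)
        if (ruleOn[8] && energy && unif_rand() < ae) {
          spawnInCyto(S_E, c); logEv(E_PROD_AE);
        }
        break;
      case S_FR:
        logEv(E_ENTRY_FR);
        if (ruleOn[10]) {
          if (energyAvail[c] > 0 && unif_rand() < fa) {
            spawnInCyto(S_A, c); consumeE(c); logEv(E_PROD_FA);
          }
          if (energyAvail[c] > 0 && unif_rand() < fi) {
            spawnInCyto(S_IKB, c); consumeE(c); logEv(E_PROD_FI);
          }
        }
        break;
      case S_M:
        logEv(E_ENTRY_M);
        if (ruleOn[14] && energy && unif_rand() < mp) {
          spawnInCyto(S_P, c); consumeE(c); logEv(E_PROD_MP);
        }
        break;
      case S_IKB:
        logEv(E_ENTRY_IKB);
        break;
      default: break;
    }
  }

  // --- collisions -----------------------------------------------------------

  // returns true if a rule fired (mover takes at most one event per tick)
  bool tryPair(int ia, int ib) {
    Mol& a = mol[ia];
    Mol& b = mol[ib];
    if (!a.alive || !b.alive) return false;
    if (a.comp != b.comp) return false;
    int s1 = a.sp, s2 = b.sp;

    // LPSR or imported P activates IKK (rule 1). The membrane-derived LPSR
    // complex is a persistent signal; an imported cytokine is consumed by the
    // receptor-mediated hand-off that activates the kinase.
    if (ruleOn[1]) {
      int sigIdx = -1, kinIdx = -1;
      if (s1 == S_IKK && !a.active && (s2 == S_LPSR || (s2 == S_P && b.active)) &&
          a.comp == C_CYTO) { kinIdx = ia; sigIdx = ib; }
      else if (s2 == S_IKK && !b.active && (s1 == S_LPSR || (s1 == S_P && a.active)) &&
               b.comp == C_CYTO) { kinIdx = ib; sigIdx = ia; }
      if (kinIdx >= 0) {
        mol[kinIdx].active = true; mol[kinIdx].last = tick;
        activeIKK[mol[kinIdx].cell]++;
        mol[sigIdx].last = tick;
        if (mol[sigIdx].sp == S_P) removeMol(sigIdx);
        logEv(E_IKK_ACT);
        return true;
      }
      // activated IKK liberates NFkB from the complex
      Mol* ikk = NULL; int complexIdx = -1;
      if (s1 == S_IKK && a.active && s2 == S_NIKB) { ikk = &a; complexIdx = ib; }
      else if (s2 == S_IKK && b.active && s1 == S_NIKB) { ikk = &b; complexIdx = ia; }
      if (ikk) {
        int c = mol[complexIdx].cell, x = mol[complexIdx].x, y = mol[complexIdx].y;
        ikk->last = tick;            // before addMol: it may reallocate mol[]
        ikk->active = false;         // kinase activity is transient: one firing
        activeIKK[ikk->cell]--;
        removeMol(complexIdx);
        addMol(S_NFKB, C_CYTO, c, x, y, false, tick);
        logEv(E_NFKB_FREED);
        return true;
      }
    }

    // NFkB + IkB -> NFkB.IkB (rule 3), complex is cytoplasmic
    if (ruleOn[3] &&
        ((s1 == S_NFKB && s2 == S_IKB) || (s1 == S_IKB && s2 == S_NFKB))) {
      int c = a.cell, x = a.x, y = a.y;
      bool inNuc = (a.comp == C_NUC);
      removeMol(ia); removeMol(ib);
      if (inNuc) { // nearest cytoplasmic position just outside the nucleus region
        int dxl = x - (nucX0 - 1), dxr = (nucX0 + nucSide) - x;
        int dyl = y - (nucY0 - 1), dyr = (nucY0 + nucSide) - y;
        int mn = std::min(std::min(dxl, dxr), std::min(dyl, dyr));
        if (mn == dxl) x = nucX0 - 1;
        else if (mn == dxr) x = nucX0 + nucSide;
        else if (mn == dyl) y = nucY0 - 1;
        else y = nucY0 + nucSide;
        if (x < 0) x = 0; if (x >= CW) x = CW - 1;
        if (y < 0) y = 0; if (y >= CH) y = CH - 1;
      }
      addMol(S_NIKB, C_CYTO, c, x, y, false, tick);
      logEv(E_COMPLEX);
      return true;
    }

    // F + GR -> FR in cytoplasm
    if (ruleOn[21] && a.comp == C_CYTO &&
        ((s1 == S_F && s2 == S_GR) || (s1 == S_GR && s2 == S_F))) {
      int c = a.cell, x = a.x, y = a.y;
      removeMol(ia); removeMol(ib);
      addMol(S_FR, C_CYTO, c, x, y, false, tick);
      logEv(E_FR_FORMED);
      return true;
    }

    // P + A with the same status annihilate (rule 9)
    if (ruleOn[9] && a.active == b.active &&
        ((s1 == S_P && s2 == S_A) || (s1 == S_A && s2 == S_P))) {
      removeMol(ia); removeMol(ib);
      logEv(E_ANNIHILATION);
      return true;
    }
    return false;
  }

  void collide(int i) {
    int p = gpos(mol[i]);
    const std::vector<int>& v = occ[p];
    // tryPair leaves occ/mol untouched unless it fires, and we return then
    for (size_t k = 0; k < v.size(); ++k) {
      int j = v[k];
      if (j == i) continue;
      if (!mol[j].alive || mol[j].comp != mol[i].comp) continue;
      if (tryPair(i, j)) return;
    }
  }

  // --- attraction -----------------------------------------------------------

  // attraction only operates for pairs whose interaction rule is enabled:
  // otherwise disabled rules would still glue molecules together
  bool attractPair(const Mol& m, const Mol& o) const {
    if (o.comp != m.comp) return false;
    int s1 = m.sp, s2 = o.sp;
    if ((s1 == S_P && s2 == S_A) || (s1 == S_A && s2 == S_P))
      return ruleOn[9] && m.active == o.active;
    if ((s1 == S_LPSR && s2 == S_IKK && !o.active) ||
        (s1 == S_IKK && !m.active && s2 == S_LPSR)) return ruleOn[1];
    if ((s1 == S_IKK && m.active && s2 == S_NIKB) ||
        (s1 == S_NIKB && s2 == S_IKK && o.active)) return ruleOn[1];
    if (m.comp == C_CYTO &&
        ((s1 == S_F && s2 == S_GR) || (s1 == S_GR && s2 == S_F)))
      return ruleOn[21];
    if ((s1 == S_NFKB && s2 == S_IKB) || (s1 == S_IKB && s2 == S_NFKB))
      return ruleOn[3];
    return false;
  }

  bool maybeAttractPartner(const Mol& m, int sp) const {
    // cheap count screen before the neighbourhood scan
    switch (sp) {
      case S_P:
        if (m.comp >= C_CYTO) return cnt[(size_t)m.cell * NSP + S_A] > 0;
        return gCnt[S_A] > 0;
      case S_A:
        if (m.comp >= C_CYTO) return cnt[(size_t)m.cell * NSP + S_P] > 0;
        return gCnt[S_P] > 0;
      case S_LPSR: return cnt[(size_t)m.cell * NSP + S_IKK] > 0;
      case S_IKK:
        return m.active ? cnt[(size_t)m.cell * NSP + S_NIKB] > 0
                        : cnt[(size_t)m.cell * NSP + S_LPSR] > 0;
      case S_NIKB: return activeIKK[m.cell] > 0;
      case S_F: return m.comp == C_CYTO && cnt[(size_t)m.cell * NSP + S_GR] > 0;
      case S_GR: return cnt[(size_t)m.cell * NSP + S_F] > 0;
      case S_NFKB: return cnt[(size_t)m.cell * NSP + S_IKB] > 0;
      case S_IKB: return cnt[(size_t)m.cell * NSP + S_NFKB] > 0;
      default: return false;
    }
  }

  // find an attraction target within Chebyshev distance < theta;
  // returns best squared... (chebyshev) distance or -1
  bool findAttraction(int i, int& tx, int& ty) const {
    const Mol& m = mol[i];
    int best = theta;  // want dist < theta
    bool found = false;
    if (maybeAttractPartner(m, m.sp)) {
      int W = (m.comp <= C_BRAIN) ? PW : CW;
      int H = (m.comp <= C_BRAIN) ? PH : CH;
      for (int dy = -(theta - 1); dy <= theta - 1; ++dy) {
        int yy = m.y + dy;
        if (yy < 0 || yy >= H) continue;
        for (int dx = -(theta - 1); dx <= theta - 1; ++dx) {
          int xx = m.x + dx;
          if (xx < 0 || xx >= W) continue;
          int d = std::max(std::abs(dx), std::abs(dy));
          if (d == 0 || d >= best) continue;
          int p = (m.comp <= C_BRAIN) ? plasmaPos(xx, yy)
                                      : cellGridPos(m.cell, xx, yy);
          const std::vector<int>& v = occ[p];
          for (size_t k = 0; k < v.size(); ++k) {
            const Mol& o = mol[v[k]];
            if (!o.alive) continue;
            if (attractPair(m, o)) { best = d; tx = xx; ty = yy; found = true; break; }
          }
        }
      }
    }
    // molecule-cell attraction in plasma
    if (m.comp == C_PLASMA &&
        (m.sp == S_LPS || m.sp == S_P || m.sp == S_A || m.sp == S_F || m.sp == S_M)) {
      int t = attrCell[plasmaPos(m.x, m.y)];
      if (t >= 0 && !(m.lastTried >= 0 && cellPos[m.lastTried] == t)) {
        int cx = t % PW, cy = t / PW;
        int d = std::max(std::abs(cx - m.x), std::abs(cy - m.y));
        if (d > 0 && d < best) { tx = cx; ty = cy; found = true; }
      }
    }
    return found;
  }

  // --- arrival handling -----------------------------------------------------

  void arriveInPlasmaSpace(int i, int nx, int ny) {
    Mol& m = mol[i];
    if (m.comp == C_PLASMA) {
      if (inBrain(nx, ny) && !inBrain(m.x, m.y)) {
        // crossing into the brain region from outside; one attempt per
        // approach - a refractory molecule must diffuse away first
        if (m.sp != S_LPS && spAllowed(m.sp, C_BRAIN) && ruleOn[5] &&
            m.lastTried != -2) {
          logEv(E_IMPORT_ATTEMPT);
          if (unif_rand() < importProb) {
            relocate(i, m.sp, C_BRAIN, -1, nx, ny);
            m.active = true; m.last = tick; m.lastTried = -1;
            logEv(E_IMPORT);
            if (m.sp == S_F) brainEntryF();
            else if (m.sp == S_P) brainEntryP();
            return;
          }
          m.lastTried = -2;
        }
        return; // failed/forbidden: stay outside
      }
      int c = cellAt[plasmaPos(nx, ny)];
      if (c >= 0 && c != m.lastTried) {
        if (m.sp == S_LPS) {
          logEv(E_LPS_ATTEMPT);
          int nb = (int)boundaryPos.size();
          int bp = boundaryPos[ri(nb)];
          int ti = tlr4At[(size_t)c * CA + bp];
          if (ti >= 0) {
            removeMol(ti); // receptor consumed, LPS becomes the bound complex
            relocate(i, S_LPSR, C_CYTO, c, bp % CW, bp / CW);
            m.active = true; m.last = tick; m.lastTried = -1;
            logEv(E_LPS_IMPORT);
            collide(i);
            return;
          }
          m.lastTried = (int16_t)c;
        } else if ((m.sp == S_P || m.sp == S_A || m.sp == S_F || m.sp == S_M) &&
                   ruleOn[5]) {
          logEv(E_IMPORT_ATTEMPT);
          if (unif_rand() < importProb) {
            int x, y; randCytoPos(c, x, y);
            relocate(i, m.sp, C_CYTO, c, x, y);
            m.active = true; m.last = tick; m.lastTried = -1;
            logEv(E_IMPORT);
            collide(i);
            return;
          }
          m.lastTried = (int16_t)c;
        }
      }
      movePos(i, nx, ny);
      // leaving the refractory target's neighbourhood re-arms the attempt
      if (m.lastTried == -2) {
        if (nx < brainX0 - theta || nx >= brainX0 + nucSide + theta ||
            ny < brainY0 - theta || ny >= brainY0 + nucSide + theta)
          m.lastTried = -1;
      } else if (m.lastTried >= 0) {
        int cp = cellPos[m.lastTried];
        int d = std::max(std::abs(cp % PW - nx), std::abs(cp / PW - ny));
        if (d > theta) m.lastTried = -1;
      }
      collide(i);
    } else { // brain
      if (!inBrain(nx, ny)) {
        if (!m.active) { // locally produced hormone is secreted to plasma
          relocate(i, m.sp, C_PLASMA, -1, nx, ny);
          m.last = tick;
        }
        // imported (active) molecules are never re-exported: stay
        return;
      }
      movePos(i, nx, ny);
      // no interactive pairs share the brain compartment
    }
  }

  void arriveInCellSpace(int i, int nx, int ny) {
    Mol& m = mol[i];
    if (m.comp == C_CYTO) {
      if (inNucleus(nx, ny)) {
        if (nucleusEligible(m) && ruleOn[17]) {
          relocate(i, m.sp, C_NUC, m.cell, nx, ny);
          m.last = tick;
          nucleusEntry(i);
          if (mol[i].alive) collide(i);
        }
        return; // others are excluded from the nucleus region
      }
      if (onCellBoundary(nx, ny) && (m.sp == S_P || m.sp == S_A) &&
          !m.active && ruleOn[4]) {
        int pp = cellPos[m.cell];
        relocate(i, m.sp, C_PLASMA, -1, pp % PW, pp / PW);
        m.last = tick;
        logEv(E_RELEASE);
        collide(i);
        return;
      }
      movePos(i, nx, ny);
      collide(i);
    } else { // nucleus
      if (!inNucleus(nx, ny)) {
        relocate(i, m.sp, C_CYTO, m.cell, nx, ny);
        m.last = tick;
        collide(i);
        return;
      }
      movePos(i, nx, ny);
      collide(i);
    }
  }

  // --- per-agent turn -------------------------------------------------------

  void turn(int i) {
    Mol& m = mol[i];
    if (!m.alive) return;
    // lazily remove an E already consumed by a stimulated production
    if (m.sp == S_E && pendingE[m.cell] > 0) {
      pendingE[m.cell]--;
      energyAvail[m.cell]++;   // removeMol will decrement it again
      removeMol(i);
      return;
    }
    if (ruleOn[20] && (tick - m.last) >= lifeTicks[m.sp]) {
      removeMol(i);
      logEv(E_DEGRADE);
      return;
    }
    if (m.immobile) return;
    if (m.wait > 0) { m.wait--; return; }

    int nx, ny, tx, ty;
    if (findAttraction(i, tx, ty)) {
      nx = m.x + (tx > m.x ? 1 : (tx < m.x ? -1 : 0));
      ny = m.y + (ty > m.y ? 1 : (ty < m.y ? -1 : 0));
    } else {
      nx = m.x + DX[(int)m.dir];
      ny = m.y + DY[(int)m.dir];
      m.steps--;
      if (m.steps <= 0) {
        m.dir = (int8_t)ri(8);
        m.steps = (int8_t)(1 + ri(persistMax));
        m.wait = (int8_t)ri(waitMax + 1);
      }
    }
    int W = (m.comp <= C_BRAIN) ? PW : CW;
    int H = (m.comp <= C_BRAIN) ? PH : CH;
    if (nx < 0) nx = 0; if (nx >= W) nx = W - 1;
    if (ny < 0) ny = 0; if (ny >= H) ny = H - 1;
    if (nx == m.x && ny == m.y) { collide(i); return; }

    if (m.comp <= C_BRAIN) arriveInPlasmaSpace(i, nx, ny);
    else arriveInCellSpace(i, nx, ny);
  }

  // --- scheduled processes --------------------------------------------------

  void defaultProduction() {
    double pTick = Rprod * (double)Sl / (double)Tsc;
    if (pTick <= 0) return;
    static const int defSp[8] = { S_TLR4, S_IKK, S_NIKB, S_IKB, S_P, S_A, S_E, S_GR };
    for (int c = 0; c < nCells; ++c) {
      for (int k = 0; k < 8; ++k) {
        int sp = defSp[k];
        if (sp == S_E && ruleOn[17] && inhibitE[c] == curHour) continue;
        if (sp == S_GR && ruleOn[12] && nucCnt[(size_t)c * NSP + S_FR] > 0) continue;
        if (unif_rand() < pTick) {
          spawnInCyto(sp, c);
          logEv(E_DEFAULT_PROD);
        }
      }
    }
    // brain produces the hormones
    if (unif_rand() < pTick) { spawnFInBrain(); logEv(E_DEFAULT_PROD); }
    if (unif_rand() < pTick) { spawnMFromBrain(); logEv(E_DEFAULT_PROD); }
  }

  double circadianProb(double hourOfDay, double wStart, double wPeak) const {
    double len = wPeak - wStart;
    if (len <= 0) len += 24.0;
    double el = hourOfDay - wStart;
    if (el < 0) el += 24.0;
    if (el > len) return 0.0;
    return std::sin(M_PI_2 * el / len);
  }

  void circadianAdditions() {
    if (!circadian) return;
    double t = startHour + (double)tick / Tsc;
    double hod = t - 24.0 * std::floor(t / 24.0);
    double scale = (double)Sl / (double)Tsc; // additions follow the life schedule
    if (ruleOn[18]) {
      double p = circadianProb(hod, fWinStart, fWinPeak) * scale;
      if (p > 0 && unif_rand() < p) {
        for (int k = 0; k < cfm; ++k) { spawnFInBrain(); logEv(E_CIRC_F); }
      }
    }
    if (ruleOn[19]) {
      double p = circadianProb(hod, mWinStart, mWinPeak) * scale;
      if (p > 0 && unif_rand() < p) {
        for (int k = 0; k < cfm; ++k) { spawnMFromBrain(); logEv(E_CIRC_M); }
      }
    }
  }

  void injectLPS(int dose) {
    for (int k = 0; k < dose; ++k) {
      int x, y;
      do { x = ri(PW); y = ri(PH); } while (inBrain(x, y));
      addMol(S_LPS, C_PLASMA, -1, x, y, false, tick);
    }
  }
};

void World::spawnFInBrain() {
  int x, y; randBrainPos(x, y);
  addMol(S_F, C_BRAIN, -1, x, y, false, tick);
  brainEntryF();
}

static void buildWorld(World& w, List cfg) {
  w.PW = as<int>(cfg["plasmaWidth"]);   w.PH = as<int>(cfg["plasmaHeight"]);
  w.CW = as<int>(cfg["cellWidth"]);     w.CH = as<int>(cfg["cellHeight"]);
  w.nucSide = as<int>(cfg["nucleusSide"]);
  w.nCells = as<int>(cfg["nCells"]);
  w.CA = w.CW * w.CH;
  w.nucX0 = (w.CW - w.nucSide) / 2;  w.nucY0 = (w.CH - w.nucSide) / 2;
  w.brainX0 = (w.PW - w.nucSide) / 2; w.brainY0 = (w.PH - w.nucSide) / 2;
  w.Sl = as<int>(cfg["lifeScale"]);  w.Tsc = as<int>(cfg["timeScale"]);
  w.startHour = as<double>(cfg["startHour"]);
  w.Rprod = as<double>(cfg["defaultRate"]);
  w.importProb = as<double>(cfg["importProb"]);
  NumericVector pr = cfg["probs"]; // kp ki fi fa fm mp pf pt ae
  w.kp = pr[0]; w.ki = pr[1]; w.fi = pr[2]; w.fa = pr[3]; w.fm = pr[4];
  w.mp = pr[5]; w.pf = pr[6]; w.pt = pr[7]; w.ae = pr[8];
  w.theta = as<int>(cfg["theta"]);
  w.cellAttractRadius = as<int>(cfg["cellAttractRadius"]);
  w.waitMax = as<int>(cfg["waitMax"]);
  w.persistMax = as<int>(cfg["persistMax"]);
  w.cfm = as<int>(cfg["cfm"]);
  NumericVector fw = cfg["cortisolWindow"], mw = cfg["melatoninWindow"];
  w.fWinStart = fw[0]; w.fWinPeak = fw[1];
  w.mWinStart = mw[0]; w.mWinPeak = mw[1];

  NumericVector hl = cfg["halfLife"];
  IntegerVector ic = cfg["initCell"];
  w.lifeTicks.resize(NSP);
  w.initCell.resize(NSP);
  for (int s = 0; s < NSP; ++s) {
    w.lifeTicks[s] = 2.0 * hl[s] * w.Tsc;
    w.initCell[s] = ic[s];
  }
  w.plasmaInitP = as<int>(cfg["plasmaInitP"]);
  w.plasmaInitA = as<int>(cfg["plasmaInitA"]);

  IntegerVector dis = cfg["disabledRules"];
  w.ruleOn.assign(22, 1);
  for (int k = 0; k < dis.size(); ++k)
    if (dis[k] >= 0 && dis[k] < 22) w.ruleOn[dis[k]] = 0;

  // state containers
  int nPos = w.PW * w.PH + w.nCells * w.CA;
  w.occ.assign(nPos, std::vector<int>());
  w.cellAt.assign(w.PW * w.PH, -1);
  w.cellPos.assign(w.nCells, -1);
  w.attrCell.assign(w.PW * w.PH, -1);
  w.tlr4At.assign((size_t)w.nCells * w.CA, -1);
  w.cnt.assign((size_t)w.nCells * NSP, 0);
  w.nucCnt.assign((size_t)w.nCells * NSP, 0);
  for (int s = 0; s < NSP; ++s) { w.brainCnt[s] = 0; w.gCnt[s] = 0; }
  w.activeIKK.assign(w.nCells, 0);
  w.energyAvail.assign(w.nCells, 0);
  w.pendingE.assign(w.nCells, 0);
  w.inhibitE.assign(w.nCells, -1);
  w.tick = 0; w.curHour = 0;

  for (int y = 0; y < w.CH; ++y)
    for (int x = 0; x < w.CW; ++x)
      if (w.onCellBoundary(x, y)) w.boundaryPos.push_back(y * w.CW + x);

  // place cells: distinct plasma points outside the brain region
  int placed = 0, guard = 0;
  while (placed < w.nCells) {
    if (++guard > 200000) stop("unable to place cells disjointly");
    int x = ri(w.PW), y = ri(w.PH);
    if (w.inBrain(x, y)) continue;
    int p = w.plasmaPos(x, y);
    if (w.cellAt[p] >= 0) continue;
    w.cellAt[p] = placed;
    w.cellPos[placed] = p;
    placed++;
  }
  // static molecule->cell attraction table; the pull applies when a
  // molecule is within cellAttractRadius of a cell (default: adjacent)
  int car = w.cellAttractRadius;
  for (int c = 0; c < w.nCells; ++c) {
    int cx = w.cellPos[c] % w.PW, cy = w.cellPos[c] / w.PW;
    for (int dy = -car; dy <= car; ++dy)
      for (int dx = -car; dx <= car; ++dx) {
        int x = cx + dx, y = cy + dy;
        if (x < 0 || x >= w.PW || y < 0 || y >= w.PH) continue;
        int d = std::max(std::abs(dx), std::abs(dy));
        if (d == 0) continue;
        int p = w.plasmaPos(x, y);
        int cur = w.attrCell[p];
        if (cur < 0) { w.attrCell[p] = w.cellPos[c]; continue; }
        int ox = cur % w.PW, oy = cur / w.PW;
        int od = std::max(std::abs(ox - x), std::abs(oy - y));
        if (d < od) w.attrCell[p] = w.cellPos[c];
      }
  }

  // populate cells; ages staggered uniformly over one lifetime
  for (int c = 0; c < w.nCells; ++c) {
    for (int s = 0; s < NSP; ++s) {
      int n = w.initCell[s];
      for (int k = 0; k < n; ++k) {
        int32_t age = -(int32_t)std::floor(unif_rand() * w.lifeTicks[s]);
        if (s == S_TLR4) {
          int x, y;
          if (!w.freeBoundaryPos(c, x, y)) break;
          w.addMol(s, C_CYTO, c, x, y, false, age, true);
        } else {
          int x, y; w.randCytoPos(c, x, y);
          w.addMol(s, C_CYTO, c, x, y, false, age);
        }
      }
    }
  }
  // plasma pools of inactive P and A
  for (int k = 0; k < w.plasmaInitP + w.plasmaInitA; ++k) {
    int sp = (k < w.plasmaInitP) ? S_P : S_A;
    int x, y;
    do { x = ri(w.PW); y = ri(w.PH); } while (w.inBrain(x, y));
    int32_t age = -(int32_t)std::floor(unif_rand() * w.lifeTicks[sp]);
    w.addMol(sp, C_PLASMA, -1, x, y, false, age);
  }
}

static DataFrame snapshot(const World& w) {
  std::vector<int> sp, comp, cell, x, y, act;
  for (size_t i = 0; i < w.mol.size(); ++i) {
    const Mol& m = w.mol[i];
    if (!m.alive) continue;
    sp.push_back(m.sp + 1);      // 1-based species index
    comp.push_back(m.comp);
    cell.push_back(m.cell < 0 ? NA_INTEGER : m.cell + 1);
    x.push_back(m.x); y.push_back(m.y);
    act.push_back(m.active ? 1 : 0);
  }
  return DataFrame::create(
    _["species"] = sp, _["compartment"] = comp, _["cell"] = cell,
    _["x"] = x, _["y"] = y, _["active"] = act);
}

// [[Rcpp::export]]
List cpp_simulate(List cfg, int hours, IntegerVector injTick, IntegerVector injDose,
                  bool circadian, bool withSnapshot) {
  World w;
  buildWorld(w, cfg);
  w.circadian = circadian;
  int H = hours < 1 ? 1 : hours;
  w.evHours = H;
  w.ev.assign((size_t)NEV * H, 0);

  int totTicks = hours * w.Tsc;
  IntegerMatrix sys(NSP, hours + 1);
  IntegerVector cellArr(Dimension(NSP, w.nCells, hours + 1));
  IntegerVector lpsr(totTicks + 1);

  // injections scheduled at tick 0 happen before the first sample
  for (int k = 0; k < injTick.size(); ++k)
    if (injTick[k] == 0) w.injectLPS(injDose[k]);

  std::vector<int> order;
  int sampleCol = 0;
  // sample hour 0
  for (int s = 0; s < NSP; ++s) sys(s, 0) = (int)w.gCnt[s];
  for (int c = 0; c < w.nCells; ++c)
    for (int s = 0; s < NSP; ++s)
      cellArr[s + NSP * (c + (size_t)w.nCells * 0)] = (int)w.cnt[(size_t)c * NSP + s];
  lpsr[0] = (int)w.gCnt[S_LPSR];
  sampleCol = 1;

  for (int tick = 1; tick <= totTicks; ++tick) {
    w.tick = tick;
    w.curHour = (tick - 1) / w.Tsc;

    // shuffled asynchronous schedule
    order.clear();
    for (size_t i = 0; i < w.mol.size(); ++i)
      if (w.mol[i].alive) order.push_back((int)i);
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = ri(i + 1);
      int t = order[i]; order[i] = order[j]; order[j] = t;
    }
    for (size_t k = 0; k < order.size(); ++k) w.turn(order[k]);

    w.defaultProduction();
    w.circadianAdditions();
    for (int k = 0; k < injTick.size(); ++k)
      if (injTick[k] == tick) w.injectLPS(injDose[k]);

    lpsr[tick] = (int)w.gCnt[S_LPSR];
    if (tick % w.Tsc == 0) {
      for (int s = 0; s < NSP; ++s) sys(s, sampleCol) = (int)w.gCnt[s];
      for (int c = 0; c < w.nCells; ++c)
        for (int s = 0; s < NSP; ++s)
          cellArr[s + NSP * (c + (size_t)w.nCells * sampleCol)] =
            (int)w.cnt[(size_t)c * NSP + s];
      sampleCol++;
    }
    if (tick % (w.Tsc * 4) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix evm(NEV, H);
  for (int e = 0; e < NEV; ++e)
    for (int h = 0; h < H; ++h)
      evm(e, h) = (double)w.ev[(size_t)e * H + h];

  List out = List::create(
    _["systemCounts"] = sys,
    _["cellCounts"] = cellArr,
    _["events"] = evm,
    _["lpsrPerTick"] = lpsr);
  if (withSnapshot) out["snapshot"] = snapshot(w);
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_world_snapshot(List cfg) {
  World w;
  buildWorld(w, cfg);
  return snapshot(w);
}

// closed-form probability ramp of the circadian drivers (exposed for tests)
// [[Rcpp::export]]
double cpp_circadian_prob(double hourOfDay, double windowStart, double windowPeak) {
  double len = windowPeak - windowStart;
  if (len <= 0) len += 24.0;
  double el = hourOfDay - windowStart;
  if (el < 0) el += 24.0;
  if (el > len) return 0.0;
  return std::sin(M_PI_2 * el / len);
}

// n uniform Moore-direction draws, 0..7 (exposed for tests of walk isotropy)
// [[Rcpp::export]]
IntegerVector cpp_direction_draws(int n) {
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ri(8);
  return out;
}
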