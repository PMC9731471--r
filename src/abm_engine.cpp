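// Lattice agent-based engine for receptor clustering.
//
// Agents live on a toroidal W x W patch grid.  Receptors carry at most one
// dimer bond, one ligand bond (extracellular epitope) and one crosslinker
// bond (cytosolic tail, phosphorylation-gated).  Divalent ligands and
// crosslinkers each carry two sites binding distinct receptors.  One tick:
// move -> unbind -> bind -> phosphorylation, with randomized agent order
// inside each phase.  All randomness comes from R's RNG so set.seed() gives
// bit-identical runs.
//
// Index convention at this boundary: 0-based, -1 = unbound.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double ru() { return unif_rand(); }

static inline int ri(int n) {            // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static void shuffle_idx(std::vector<int>& v) {  // Fisher-Yates
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = ri(i + 1);
    std::swap(v[i], v[j]);
  }
}

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  }
};

struct World {
  int W, nR, nL, nX;
  std::vector<int> rx, ry, phos, dimer, lig, ligsite, xl, xlsite;
  std::vector<int> lx, ly, ls1, ls2;
  std::vector<int> xx, xy, xs1, xs2;
  int tick;
};

struct Cfg {
  double p_phos_on, p_phos_off, p_dim_on, p_dim_off;
  double p_xl_on, p_xl_off, p_lig_on, p_lig_off;
  double lig_phos_mult;
  bool cluster_slowdown;
};

static const int DX[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DY[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static World world_from_list(List w) {
  World s;
  s.W = as<int>(w["width"]);
  s.tick = as<int>(w["tick"]);
  IntegerVector rx = w["rx"];
  s.nR = rx.size();
  s.rx = as<std::vector<int> >(w["rx"]);
  s.ry = as<std::vector<int> >(w["ry"]);
  s.phos = as<std::vector<int> >(w["phos"]);
  s.dimer = as<std::vector<int> >(w["dimer"]);
  s.lig = as<std::vector<int> >(w["lig"]);
  s.ligsite = as<std::vector<int> >(w["ligsite"]);
  s.xl = as<std::vector<int> >(w["xl"]);
  s.xlsite = as<std::vector<int> >(w["xlsite"]);
  s.lx = as<std::vector<int> >(w["lx"]);
  s.ly = as<std::vector<int> >(w["ly"]);
  s.ls1 = as<std::vector<int> >(w["ls1"]);
  s.ls2 = as<std::vector<int> >(w["ls2"]);
  s.xx = as<std::vector<int> >(w["xx"]);
  s.xy = as<std::vector<int> >(w["xy"]);
  s.xs1 = as<std::vector<int> >(w["xs1"]);
  s.xs2 = as<std::vector<int> >(w["xs2"]);
  s.nL = s.lx.size();
  s.nX = s.xx.size();
  return s;
}

static List world_to_list(const World& s) {
  return List::create(
    _["width"] = s.W, _["tick"] = s.tick,
    _["rx"] = wrap(s.rx), _["ry"] = wrap(s.ry), _["phos"] = wrap(s.phos),
    _["dimer"] = wrap(s.dimer), _["lig"] = wrap(s.lig),
    _["ligsite"] = wrap(s.ligsite), _["xl"] = wrap(s.xl),
    _["xlsite"] = wrap(s.xlsite),
    _["lx"] = wrap(s.lx), _["ly"] = wrap(s.ly),
    _["ls1"] = wrap(s.ls1), _["ls2"] = wrap(s.ls2),
    _["xx"] = wrap(s.xx), _["xy"] = wrap(s.xy),
    _["xs1"] = wrap(s.xs1), _["xs2"] = wrap(s.xs2));
}

// union-find over all agents (receptors, then ligands, then crosslinkers)
// following every bond; used for joint movement of bound complexes.
static void unite_bonds(const World& s, UF& uf) {
  int offL = s.nR, offX = s.nR + s.nL;
  for (int i = 0; i < s.nR; ++i)
    if (s.dimer[i] > i) uf.unite(i, s.dimer[i]);
  for (int l = 0; l < s.nL; ++l) {
    if (s.ls1[l] >= 0) uf.unite(offL + l, s.ls1[l]);
    if (s.ls2[l] >= 0) uf.unite(offL + l, s.ls2[l]);
  }
  for (int x = 0; x < s.nX; ++x) {
    if (s.xs1[x] >= 0) uf.unite(offX + x, s.xs1[x]);
    if (s.xs2[x] >= 0) uf.unite(offX + x, s.xs2[x]);
  }
}

static void phase_move(World& s, const Cfg& c) {
  int n = s.nR + s.nL + s.nX;
  UF uf(n);
  unite_bonds(s, uf);
  // receptor count per component root
  std::vector<int> rcount(n, 0);
  for (int i = 0; i < s.nR; ++i) rcount[uf.find(i)]++;
  // per-root displacement (sentinel 9 = not decided yet)
  std::vector<int> mdx(n, 9), mdy(n, 9);
  for (int a = 0; a < n; ++a) {
    int r = uf.find(a);
    if (mdx[r] == 9) {
      int sz = rcount[r];
      bool moves = true;
      if (c.cluster_slowdown && sz > 3) moves = (ru() < 1.0 / sz);
      if (moves) {
        int d = ri(8);
        mdx[r] = DX[d]; mdy[r] = DY[d];
      } else {
        mdx[r] = 0; mdy[r] = 0;
      }
    }
    int dx = mdx[r], dy = mdy[r];
    if (dx == 0 && dy == 0) continue;
    if (a < s.nR) {
      s.rx[a] = (s.rx[a] + dx + s.W) % s.W;
      s.ry[a] = (s.ry[a] + dy + s.W) % s.W;
    } else if (a < s.nR + s.nL) {
      int l = a - s.nR;
      s.lx[l] = (s.lx[l] + dx + s.W) % s.W;
      s.ly[l] = (s.ly[l] + dy + s.W) % s.W;
    } else {
      int x = a - s.nR - s.nL;
      s.xx[x] = (s.xx[x] + dx + s.W) % s.W;
      s.xy[x] = (s.xy[x] + dy + s.W) % s.W;
    }
  }
}

static void phase_unbind(World& s, const Cfg& c) {
  for (int i = 0; i < s.nR; ++i) {
    int j = s.dimer[i];
    if (j > i && ru() < c.p_dim_off) {
      s.dimer[i] = -1;
      s.dimer[j] = -1;
    }
  }
  for (int l = 0; l < s.nL; ++l) {
    if (s.ls1[l] >= 0 && ru() < c.p_lig_off) {
      s.lig[s.ls1[l]] = -1; s.ligsite[s.ls1[l]] = -1; s.ls1[l] = -1;
    }
    if (s.ls2[l] >= 0 && ru() < c.p_lig_off) {
      s.lig[s.ls2[l]] = -1; s.ligsite[s.ls2[l]] = -1; s.ls2[l] = -1;
    }
  }
  for (int x = 0; x < s.nX; ++x) {
    if (s.xs1[x] >= 0 && ru() < c.p_xl_off) {
      s.xl[s.xs1[x]] = -1; s.xlsite[s.xs1[x]] = -1; s.xs1[x] = -1;
    }
    if (s.xs2[x] >= 0 && ru() < c.p_xl_off) {
      s.xl[s.xs2[x]] = -1; s.xlsite[s.xs2[x]] = -1; s.xs2[x] = -1;
    }
  }
}

// patch bucket of receptors: head[patch] / nxt[receptor] linked lists
static void bucket_receptors(const World& s, std::vector<int>& head,
                             std::vector<int>& nxt) {
  head.assign(s.W * s.W, -1);
  nxt.assign(s.nR, -1);
  for (int i = 0; i < s.nR; ++i) {
    int p = s.rx[i] * s.W + s.ry[i];
    nxt[i] = head[p];
    head[p] = i;
  }
}

// uniform random receptor in contact range (Chebyshev radius 1, own patch
// plus the 8 neighbours, toroidal) of (x, y) satisfying pred, together with
// the number of such receptors; chosen = -1 if none.  Reservoir sampling
// over the patch bucket lists.
struct ContactPick { int chosen; int count; };

template <class Pred>
static ContactPick pick_in_contact(const World& s,
                                   const std::vector<int>& head,
                                   const std::vector<int>& nxt, int x, int y,
                                   Pred pred) {
  ContactPick r = {-1, 0};
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      int p = ((x + dx + s.W) % s.W) * s.W + (y + dy + s.W) % s.W;
      for (int i = head[p]; i >= 0; i = nxt[i]) {
        if (pred(i)) {
          ++r.count;
          if (ri(r.count) == 0) r.chosen = i;
        }
      }
    }
  }
  return r;
}

// a binding site attempts one Bernoulli(p) trial against every eligible
// contact: success probability 1 - (1-p)^k for k candidates (bimolecular
// collision scaling); the partner is uniform among the candidates.
static inline bool site_binds(double p, int k) {
  if (k <= 0 || p <= 0) return false;
  double p_any = 1.0 - std::pow(1.0 - p, (double)k);
  return ru() < p_any;
}

static void phase_bind(World& s, const Cfg& c) {
  std::vector<int> head, nxt;
  bucket_receptors(s, head, nxt);

  // live component structure over receptors: a divalent agent's second site
  // only engages a receptor from a different complex (a within-complex
  // bridge cannot change the complex census; it would only sequester the
  // agent, an artefact of same-patch stacking of bound complexes).
  UF comp(s.nR);
  for (int i = 0; i < s.nR; ++i)
    if (s.dimer[i] > i) comp.unite(i, s.dimer[i]);
  for (int l = 0; l < s.nL; ++l)
    if (s.ls1[l] >= 0 && s.ls2[l] >= 0) comp.unite(s.ls1[l], s.ls2[l]);
  for (int x = 0; x < s.nX; ++x)
    if (s.xs1[x] >= 0 && s.xs2[x] >= 0) comp.unite(s.xs1[x], s.xs2[x]);

  // receptor-receptor dimerisation, randomized receptor order
  if (c.p_dim_on > 0 && s.nR > 1) {
    std::vector<int> ord(s.nR);
    for (int i = 0; i < s.nR; ++i) ord[i] = i;
    shuffle_idx(ord);
    for (int k = 0; k < s.nR; ++k) {
      int i = ord[k];
      if (s.dimer[i] >= 0) continue;
      ContactPick pk = pick_in_contact(s, head, nxt, s.rx[i], s.ry[i],
                                       [&](int q) {
        return q != i && s.dimer[q] < 0;
      });
      if (pk.chosen >= 0 && site_binds(c.p_dim_on, pk.count)) {
        int j = pk.chosen;
        s.dimer[i] = j;
        s.dimer[j] = i;
        comp.unite(i, j);
      }
    }
  }

  // divalent ligand epitopes (a receptor holds at most one ligand bond)
  if (c.p_lig_on > 0 && s.nL > 0) {
    std::vector<int> ord(s.nL);
    for (int l = 0; l < s.nL; ++l) ord[l] = l;
    shuffle_idx(ord);
    for (int k = 0; k < s.nL; ++k) {
      int l = ord[k];
      for (int site = 0; site < 2; ++site) {
        int cur = site == 0 ? s.ls1[l] : s.ls2[l];
        if (cur >= 0) continue;
        int other = site == 0 ? s.ls2[l] : s.ls1[l];
        ContactPick pk = pick_in_contact(s, head, nxt, s.lx[l], s.ly[l],
                                         [&](int q) {
          if (s.lig[q] >= 0) return false;
          return other < 0 || comp.find(q) != comp.find(other);
        });
        if (pk.chosen >= 0 && site_binds(c.p_lig_on, pk.count)) {
          int i = pk.chosen;
          if (site == 0) s.ls1[l] = i; else s.ls2[l] = i;
          s.lig[i] = l;
          s.ligsite[i] = site;
          if (other >= 0) comp.unite(i, other);
        }
      }
    }
  }

  // crosslinker sites: phosphorylated receptors with a free tail only
  if (c.p_xl_on > 0 && s.nX > 0) {
    std::vector<int> ord(s.nX);
    for (int x = 0; x < s.nX; ++x) ord[x] = x;
    shuffle_idx(ord);
    for (int k = 0; k < s.nX; ++k) {
      int x = ord[k];
      for (int site = 0; site < 2; ++site) {
        int cur = site == 0 ? s.xs1[x] : s.xs2[x];
        if (cur >= 0) continue;
        int other = site == 0 ? s.xs2[x] : s.xs1[x];
        ContactPick pk = pick_in_contact(s, head, nxt, s.xx[x], s.xy[x],
                                         [&](int q) {
          if (s.phos[q] != 1 || s.xl[q] >= 0) return false;
          return other < 0 || comp.find(q) != comp.find(other);
        });
        if (pk.chosen >= 0 && site_binds(c.p_xl_on, pk.count)) {
          int i = pk.chosen;
          if (site == 0) s.xs1[x] = i; else s.xs2[x] = i;
          s.xl[i] = x;
          s.xlsite[i] = site;
          if (other >= 0) comp.unite(i, other);
        }
      }
    }
  }
}

static void phase_phos(World& s, const Cfg& c) {
  for (int i = 0; i < s.nR; ++i) {
    if (s.phos[i] == 0) {
      double p = c.p_phos_on;
      if (s.lig[i] >= 0) p *= c.lig_phos_mult;
      if (p > 1.0) p = 1.0;
      if (ru() < p) s.phos[i] = 1;
    } else if (s.xl[i] < 0) {
      // a crosslinker-occupied tail is protected from dephosphorylation
      if (ru() < c.p_phos_off) s.phos[i] = 0;
    }
  }
}

// census over the receptor-only bond graph: edges are dimer bonds plus
// receptor pairs sharing one fully occupied ligand or crosslinker.
// row: tick, n1, n2, n3, n4, n_gt4, rec_gt4, max_size, n_phos
static void census_row(const World& s, double* row) {
  UF uf(s.nR);
  for (int i = 0; i < s.nR; ++i)
    if (s.dimer[i] > i) uf.unite(i, s.dimer[i]);
  for (int l = 0; l < s.nL; ++l)
    if (s.ls1[l] >= 0 && s.ls2[l] >= 0) uf.unite(s.ls1[l], s.ls2[l]);
  for (int x = 0; x < s.nX; ++x)
    if (s.xs1[x] >= 0 && s.xs2[x] >= 0) uf.unite(s.xs1[x], s.xs2[x]);
  std::vector<int> size(s.nR, 0);
  for (int i = 0; i < s.nR; ++i) size[uf.find(i)]++;
  int n1 = 0, n2 = 0, n3 = 0, n4 = 0, ngt4 = 0, rgt4 = 0, maxs = 0, nphos = 0;
  for (int i = 0; i < s.nR; ++i) {
    int sz = size[i];
    if (sz == 0) continue;
    if (sz == 1) n1++;
    else if (sz == 2) n2++;
    else if (sz == 3) n3++;
    else if (sz == 4) n4++;
    else { ngt4++; rgt4 += sz; }
    if (sz > maxs) maxs = sz;
  }
  for (int i = 0; i < s.nR; ++i) nphos += s.phos[i];
  row[0] = s.tick; row[1] = n1; row[2] = n2; row[3] = n3; row[4] = n4;
  row[5] = ngt4; row[6] = rgt4; row[7] = maxs; row[8] = nphos;
}

static Cfg cfg_from_list(List cfg) {
  Cfg c;
  c.p_phos_on = as<double>(cfg["p_phos_on"]);
  c.p_phos_off = as<double>(cfg["p_phos_off"]);
  c.p_dim_on = as<double>(cfg["p_dim_on"]);
  c.p_dim_off = as<double>(cfg["p_dim_off"]);
  c.p_xl_on = as<double>(cfg["p_xl_on"]);
  c.p_xl_off = as<double>(cfg["p_xl_off"]);
  c.p_lig_on = as<double>(cfg["p_lig_on"]);
  c.p_lig_off = as<double>(cfg["p_lig_off"]);
  c.lig_phos_mult = as<double>(cfg["ligand_bound_phos_multiplier"]);
  c.cluster_slowdown = as<bool>(cfg["cluster_slowdown"]);
  return c;
}

// [[Rcpp::export]]
List abm_engine(List world, List cfg, int n_ticks, int census_stride) {
  World s = world_from_list(world);
  Cfg c = cfg_from_list(cfg);
  int n_rows = 0;
  if (census_stride > 0) {
    for (int t = 1; t <= n_ticks; ++t)
      if (t % census_stride == 0 || t == n_ticks) ++n_rows;
  }
  NumericMatrix census(n_rows, 9);
  int row = 0;
  for (int t = 0; t < n_ticks; ++t) {
    phase_move(s, c);
    phase_unbind(s, c);
    phase_bind(s, c);
    phase_phos(s, c);
    s.tick++;
    if (census_stride > 0 &&
        ((t + 1) % census_stride == 0 || t + 1 == n_ticks)) {
      double tmp[9];
      census_row(s, tmp);
      for (int j = 0; j < 9; ++j) census(row, j) = tmp[j];
      ++row;
    }
  }
  return List::create(_["world"] = world_to_list(s),
                      _["census"] = census);
}

// [[Rcpp::export]]
NumericVector abm_census_cpp(List world) {
  World s = world_from_list(world);
  NumericVector out(9);
  double tmp[9];
  census_row(s, tmp);
  for (int j = 0; j < 9; ++j) out[j] = tmp[j];
  return out;
}
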