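// Direct-method stochastic simulation of site-level binding/unbinding among
// multivalent protein copies, with per-rule aggregated propensities, lazy
// eligible-pair sampling, incremental complex (connected component) tracking,
// and canonical complex keys computed at snapshot times.
//
// Canonical keys:
//  * tree components (the only kind reachable when intra-complex binding is
//    disallowed): rooted canonical form (AHU) minimized over the 1-2 tree
//    centroids; node labels are species names, edge labels carry
//    rule id + the site name on each endpoint, oriented parent->child.
//  * general components (rings/multi-edges, reachable only when intra-complex
//    binding is enabled): 1-dimensional color refinement followed by
//    exhaustive individualization (minimum encoding over every branch of the
//    search tree), correct for arbitrary labeled multigraphs at the small
//    sizes where rings occur.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <queue>
#include <random>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// canonical keys
// ---------------------------------------------------------------------------

struct LGraph {
  int n;
  std::vector<std::string> label;                 // node labels (species)
  std::vector<int> ea, eb;                        // edge endpoints, 0-based
  std::vector<std::string> rule, sa, sb;          // rule id, site at ea, site at eb
};

static std::string site_on(const LGraph& g, int e, int v) {
  return (g.ea[e] == v) ? g.sa[e] : g.sb[e];
}
static std::string site_off(const LGraph& g, int e, int v) {
  return (g.ea[e] == v) ? g.sb[e] : g.sa[e];
}

// rooted canonical string of a tree
static std::string tree_enc(const LGraph& g,
                            const std::vector<std::vector<std::pair<int, int>>>& adj,
                            int v, int pe) {
  std::vector<std::string> kids;
  for (const auto& pr : adj[v]) {
    if (pr.first == pe) continue;
    int e = pr.first, u = pr.second;
    kids.push_back("[" + g.rule[e] + "/" + site_on(g, e, v) + "/" +
                   site_off(g, e, v) + "]" + tree_enc(g, adj, u, e));
  }
  std::sort(kids.begin(), kids.end());
  std::string out = "(" + g.label[v];
  for (const auto& k : kids) out += k;
  out += ")";
  return out;
}

static std::string tree_key(const LGraph& g) {
  int n = g.n;
  std::vector<std::vector<std::pair<int, int>>> adj(n);
  for (size_t e = 0; e < g.ea.size(); ++e) {
    adj[g.ea[e]].push_back({(int)e, g.eb[e]});
    adj[g.eb[e]].push_back({(int)e, g.ea[e]});
  }
  if (n == 1) return "(" + g.label[0] + ")";
  // centroid(s) via subtree sizes from an iterative DFS rooted at 0
  std::vector<int> order, parent(n, -1), sz(n, 1);
  order.reserve(n);
  std::vector<int> stack{0};
  std::vector<char> seen(n, 0);
  seen[0] = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (const auto& pr : adj[v])
      if (!seen[pr.second]) {
        seen[pr.second] = 1;
        parent[pr.second] = v;
        stack.push_back(pr.second);
      }
  }
  for (int i = n - 1; i > 0; --i) sz[parent[order[i]]] += sz[order[i]];
  int best = n + 1;
  std::vector<int> cents;
  for (int v = 0; v < n; ++v) {
    int mx = n - sz[v];
    for (const auto& pr : adj[v])
      if (parent[pr.second] == v) mx = std::max(mx, sz[pr.second]);
    if (mx < best) {
      best = mx;
      cents.clear();
      cents.push_back(v);
    } else if (mx == best) {
      cents.push_back(v);
    }
  }
  std::string key;
  for (int c : cents) {
    std::string k = tree_enc(g, adj, c, -1);
    if (key.empty() || k < key) key = k;
  }
  return key;
}

// encoding of a general labeled multigraph under a discrete coloring
static std::string generic_encode(const LGraph& g, const std::vector<long long>& col) {
  int n = g.n;
  std::vector<int> pos(n), ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return col[a] < col[b]; });
  for (int i = 0; i < n; ++i) pos[ord[i]] = i;
  std::string nodes;
  for (int i = 0; i < n; ++i) {
    if (i) nodes += ",";
    nodes += g.label[ord[i]];
  }
  std::vector<std::string> es;
  for (size_t e = 0; e < g.ea.size(); ++e) {
    int a = g.ea[e], b = g.eb[e];
    int pa = pos[a], pb = pos[b];
    std::string lab;
    if (pa < pb || (pa == pb && g.sa[e] <= g.sb[e]))
      lab = std::to_string(pa) + "-" + std::to_string(pb) + ":" + g.rule[e] +
            "/" + g.sa[e] + "/" + g.sb[e];
    else
      lab = std::to_string(pb) + "-" + std::to_string(pa) + ":" + g.rule[e] +
            "/" + g.sb[e] + "/" + g.sa[e];
    es.push_back(lab);
  }
  std::sort(es.begin(), es.end());
  std::string out = "{" + nodes + "#";
  for (size_t i = 0; i < es.size(); ++i) {
    if (i) out += ";";
    out += es[i];
  }
  out += "}";
  return out;
}

// color refinement; colors are replaced by their lexicographic signature rank
static void refine(const LGraph& g,
                   const std::vector<std::vector<std::pair<int, int>>>& adj,
                   std::vector<long long>& col) {
  int n = g.n;
  size_t ncol = 0;
  {
    std::map<long long, int> u;
    for (int v = 0; v < n; ++v) u[col[v]] = 1;
    ncol = u.size();
  }
  while (true) {
    std::vector<std::string> sig(n);
    for (int v = 0; v < n; ++v) {
      std::vector<std::string> inc;
      for (const auto& pr : adj[v]) {
        int e = pr.first, u = pr.second;
        inc.push_back(g.rule[e] + "/" + site_on(g, e, v) + "/" +
                      site_off(g, e, v) + ":" + std::to_string(col[u]));
      }
      std::sort(inc.begin(), inc.end());
      sig[v] = std::to_string(col[v]) + "|";
      for (const auto& s : inc) sig[v] += s + ";";
    }
    std::map<std::string, long long> rank;
    for (int v = 0; v < n; ++v) rank[sig[v]] = 0;
    long long r = 0;
    for (auto& kv : rank) kv.second = r++;
    for (int v = 0; v < n; ++v) col[v] = rank[sig[v]];
    if ((size_t)r == ncol) break;
    ncol = (size_t)r;
  }
}

static void generic_search(const LGraph& g,
                           const std::vector<std::vector<std::pair<int, int>>>& adj,
                           std::vector<long long> col, std::string& best) {
  refine(g, adj, col);
  int n = g.n;
  // find first non-singleton color class (smallest color value)
  std::map<long long, std::vector<int>> cls;
  for (int v = 0; v < n; ++v) cls[col[v]].push_back(v);
  const std::vector<int>* cell = nullptr;
  for (const auto& kv : cls)
    if (kv.second.size() > 1) {
      cell = &kv.second;
      break;
    }
  if (!cell) {
    std::string enc = generic_encode(g, col);
    if (best.empty() || enc < best) best = enc;
    return;
  }
  for (int v : *cell) {
    std::vector<long long> c2(n);
    for (int u = 0; u < n; ++u) c2[u] = 2 * col[u];
    c2[v] -= 1;  // individualize v just below its class
    generic_search(g, adj, c2, best);
  }
}

static std::string generic_key(const LGraph& g) {
  int n = g.n;
  std::vector<std::vector<std::pair<int, int>>> adj(n);
  for (size_t e = 0; e < g.ea.size(); ++e) {
    adj[g.ea[e]].push_back({(int)e, g.eb[e]});
    if (g.ea[e] != g.eb[e]) adj[g.eb[e]].push_back({(int)e, g.ea[e]});
  }
  // initial colors from node labels
  std::map<std::string, long long> lr;
  for (int v = 0; v < n; ++v) lr[g.label[v]] = 0;
  long long r = 0;
  for (auto& kv : lr) kv.second = r++;
  std::vector<long long> col(n);
  for (int v = 0; v < n; ++v) col[v] = lr[g.label[v]];
  std::string best;
  generic_search(g, adj, col, best);
  return best;
}

static std::string component_key(const LGraph& g) {
  if ((int)g.ea.size() == g.n - 1) return tree_key(g);
  return generic_key(g);
}

// [[Rcpp::export]]
std::string cpp_canonical_key(CharacterVector node_species, IntegerMatrix edges,
                              CharacterVector edge_rule, CharacterVector edge_site_a,
                              CharacterVector edge_site_b) {
  LGraph g;
  g.n = node_species.size();
  for (int i = 0; i < g.n; ++i) g.label.push_back(as<std::string>(node_species[i]));
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a < 0 || a >= g.n || b < 0 || b >= g.n)
      stop("edge endpoint out of range");
    g.ea.push_back(a);
    g.eb.push_back(b);
    g.rule.push_back(as<std::string>(edge_rule[e]));
    g.sa.push_back(as<std::string>(edge_site_a[e]));
    g.sb.push_back(as<std::string>(edge_site_b[e]));
  }
  // connectivity check
  if (g.n > 0) {
    std::vector<char> seen(g.n, 0);
    std::vector<int> st{0};
    seen[0] = 1;
    int cnt = 1;
    std::vector<std::vector<int>> nb(g.n);
    for (int e = 0; e < m; ++e) {
      nb[g.ea[e]].push_back(g.eb[e]);
      nb[g.eb[e]].push_back(g.ea[e]);
    }
    while (!st.empty()) {
      int v = st.back();
      st.pop_back();
      for (int u : nb[v])
        if (!seen[u]) {
          seen[u] = 1;
          ++cnt;
          st.push_back(u);
        }
    }
    if (cnt != g.n) stop("graph is not connected; split into components first");
  }
  return component_key(g);
}

// ---------------------------------------------------------------------------
// simulation engine
// ---------------------------------------------------------------------------

struct Engine {
  // model
  int S = 0, C = 0, R = 0;
  std::vector<int> class_species;
  std::vector<std::string> class_site;
  std::vector<std::vector<std::pair<int, int>>> species_slots;  // (class, mult)
  std::vector<int> rule_a, rule_b;
  std::vector<double> kon, koff;
  std::vector<std::string> rule_ids;
  std::vector<std::string> species_names;
  bool allow_intra = false;

  // state
  int NI = 0, NS = 0;
  std::vector<int> inst_species;
  std::vector<int> slot_class, slot_inst, slot_bond;
  std::vector<std::vector<int>> inst_slots;
  std::vector<std::vector<int>> inst_bonds;

  std::vector<std::vector<int>> free_pool;  // per class
  std::vector<int> slot_free_pos;
  std::vector<long long> Ffree;  // per class

  std::vector<int> comp_of;  // per instance
  std::vector<std::vector<int>> comp_members;
  std::vector<int> inst_mpos;  // position of instance within its comp_members
  std::vector<std::vector<long long>> comp_free;  // per comp, per class
  std::vector<char> comp_alive;
  std::vector<int> comp_spare;

  std::vector<int> bond_rule, bond_s1, bond_s2;
  std::vector<char> bond_alive;
  std::vector<std::vector<int>> rule_bonds;
  std::vector<int> bond_pos;
  std::vector<int> bond_spare;

  std::vector<double> intra;  // per rule: sum over comps of eligible-within-comp pairs

  std::mt19937_64 rng;
  std::uniform_real_distribution<double> U{0.0, 1.0};

  std::vector<int> mark;
  int mark_t = 0;
  std::vector<int> side_a, side_b;  // reusable BFS buffers

  long long n_events = 0;

  double runif01() {
    double u;
    do { u = U(rng); } while (u <= 0.0 || u >= 1.0);
    return u;
  }
  int rint(int n) {  // uniform on 0..n-1
    return (int)(rng() % (uint64_t)n);
  }

  void intra_sign(int c, double sgn) {
    for (int r = 0; r < R; ++r) {
      long long fa = comp_free[c][rule_a[r]];
      if (rule_a[r] == rule_b[r])
        intra[r] += sgn * 0.5 * (double)fa * (double)(fa - 1);
      else
        intra[r] += sgn * (double)fa * (double)comp_free[c][rule_b[r]];
    }
  }

  void free_add(int s) {
    int c = slot_class[s];
    slot_free_pos[s] = free_pool[c].size();
    free_pool[c].push_back(s);
    ++Ffree[c];
  }
  void free_rm(int s) {
    int c = slot_class[s];
    int p = slot_free_pos[s];
    int last = free_pool[c].back();
    free_pool[c][p] = last;
    slot_free_pos[last] = p;
    free_pool[c].pop_back();
    --Ffree[c];
  }

  void init(List cm, IntegerVector counts, uint64_t seed) {
    S = as<int>(cm["n_species"]);
    species_names = as<std::vector<std::string>>(cm["species_names"]);
    class_species = as<std::vector<int>>(cm["class_species"]);  // 0-based
    class_site = as<std::vector<std::string>>(cm["class_site"]);
    C = class_species.size();
    List sl = cm["species_slots"];  // per species: matrix (class0, mult)
    species_slots.resize(S);
    for (int s = 0; s < S; ++s) {
      IntegerMatrix m = sl[s];
      for (int i = 0; i < m.nrow(); ++i)
        species_slots[s].push_back({m(i, 0), m(i, 1)});
    }
    rule_a = as<std::vector<int>>(cm["rule_a"]);
    rule_b = as<std::vector<int>>(cm["rule_b"]);
    kon = as<std::vector<double>>(cm["k_on"]);
    koff = as<std::vector<double>>(cm["k_off"]);
    rule_ids = as<std::vector<std::string>>(cm["rule_ids"]);
    R = rule_a.size();
    allow_intra = as<bool>(cm["allow_intra"]);
    rng.seed(seed);

    free_pool.assign(C, {});
    Ffree.assign(C, 0);
    intra.assign(R, 0.0);
    rule_bonds.assign(R, {});

    for (int s = 0; s < S; ++s)
      for (int k = 0; k < counts[s]; ++k) {
        int i = NI++;
        inst_species.push_back(s);
        inst_slots.push_back({});
        inst_bonds.push_back({});
        comp_of.push_back(i);
        inst_mpos.push_back(0);
        comp_members.push_back({i});
        comp_free.push_back(std::vector<long long>(C, 0));
        comp_alive.push_back(1);
        for (const auto& cs : species_slots[s])
          for (int j = 0; j < cs.second; ++j) {
            int sid = NS++;
            slot_class.push_back(cs.first);
            slot_inst.push_back(i);
            slot_bond.push_back(-1);
            slot_free_pos.push_back(-1);
            inst_slots[i].push_back(sid);
            comp_free[i][cs.first]++;
          }
      }
    for (int s = 0; s < NS; ++s) free_add(s);
    for (int c = 0; c < NI; ++c) intra_sign(c, +1.0);
    mark.assign(NI, 0);
  }

  double assoc_pairs(int r) const {
    int ca = rule_a[r], cb = rule_b[r];
    double tot = (ca == cb) ? 0.5 * (double)Ffree[ca] * (double)(Ffree[ca] - 1)
                            : (double)Ffree[ca] * (double)Ffree[cb];
    if (!allow_intra) tot -= intra[r];
    if (tot < 0) tot = 0;  // numerical guard
    return tot;
  }

  void make_bond(int s1, int s2, int r) {
    int i1 = slot_inst[s1], i2 = slot_inst[s2];
    int c1 = comp_of[i1], c2 = comp_of[i2];
    intra_sign(c1, -1.0);
    if (c2 != c1) intra_sign(c2, -1.0);
    int bid;
    if (!bond_spare.empty()) {
      bid = bond_spare.back();
      bond_spare.pop_back();
      bond_rule[bid] = r;
      bond_s1[bid] = s1;
      bond_s2[bid] = s2;
      bond_alive[bid] = 1;
    } else {
      bid = bond_rule.size();
      bond_rule.push_back(r);
      bond_s1.push_back(s1);
      bond_s2.push_back(s2);
      bond_alive.push_back(1);
      bond_pos.push_back(-1);
    }
    bond_pos[bid] = rule_bonds[r].size();
    rule_bonds[r].push_back(bid);
    slot_bond[s1] = bid;
    slot_bond[s2] = bid;
    free_rm(s1);
    free_rm(s2);
    comp_free[c1][slot_class[s1]]--;
    comp_free[c2][slot_class[s2]]--;
    inst_bonds[i1].push_back(bid);
    if (i2 != i1) inst_bonds[i2].push_back(bid);
    if (c1 != c2) {  // merge smaller into larger
      int big = c1, small = c2;
      if (comp_members[big].size() < comp_members[small].size())
        std::swap(big, small);
      for (int m : comp_members[small]) {
        comp_of[m] = big;
        inst_mpos[m] = comp_members[big].size();
        comp_members[big].push_back(m);
      }
      for (int c = 0; c < (int)Ffree.size(); ++c)
        comp_free[big][c] += comp_free[small][c];
      comp_members[small].clear();
      comp_alive[small] = 0;
      comp_spare.push_back(small);
      intra_sign(big, +1.0);
    } else {
      intra_sign(c1, +1.0);
    }
  }

  void break_bond(int bid) {
    int r = bond_rule[bid];
    int s1 = bond_s1[bid], s2 = bond_s2[bid];
    int i1 = slot_inst[s1], i2 = slot_inst[s2];
    int c = comp_of[i1];
    intra_sign(c, -1.0);
    // unregister bond
    {
      int p = bond_pos[bid];
      int last = rule_bonds[r].back();
      rule_bonds[r][p] = last;
      bond_pos[last] = p;
      rule_bonds[r].pop_back();
      bond_alive[bid] = 0;
      bond_spare.push_back(bid);
    }
    auto rm_inst_bond = [&](int i) {
      auto& v = inst_bonds[i];
      for (size_t k = 0; k < v.size(); ++k)
        if (v[k] == bid) {
          v[k] = v.back();
          v.pop_back();
          break;
        }
    };
    rm_inst_bond(i1);
    if (i2 != i1) rm_inst_bond(i2);
    slot_bond[s1] = -1;
    slot_bond[s2] = -1;
    free_add(s1);
    free_add(s2);
    comp_free[c][slot_class[s1]]++;
    comp_free[c][slot_class[s2]]++;
    if (i1 == i2) {  // self-loop: never splits
      intra_sign(c, +1.0);
      return;
    }
    // Bidirectional search from the two endpoints, expanding alternately;
    // the side that closes first is the (weakly) smaller piece, so leaf
    // detachments — the common case — cost O(1). If the frontiers meet
    // (possible only with rings) the component stays connected.
    int m1 = ++mark_t, m2 = ++mark_t;
    side_a.clear();
    side_b.clear();
    side_a.push_back(i1);
    side_b.push_back(i2);
    mark[i1] = m1;
    mark[i2] = m2;
    size_t qa = 0, qb = 0;
    bool joined = false;
    std::vector<int>* winner = nullptr;
    while (true) {
      if (qa < side_a.size()) {
        int v = side_a[qa++];
        for (int b : inst_bonds[v]) {
          int w1 = slot_inst[bond_s1[b]], w2 = slot_inst[bond_s2[b]];
          int u = (w1 == v) ? w2 : w1;
          if (mark[u] == m2) {
            joined = true;
            break;
          }
          if (mark[u] != m1) {
            mark[u] = m1;
            side_a.push_back(u);
          }
        }
        if (joined) break;
      } else {
        winner = &side_a;
        break;
      }
      if (qb < side_b.size()) {
        int v = side_b[qb++];
        for (int b : inst_bonds[v]) {
          int w1 = slot_inst[bond_s1[b]], w2 = slot_inst[bond_s2[b]];
          int u = (w1 == v) ? w2 : w1;
          if (mark[u] == m1) {
            joined = true;
            break;
          }
          if (mark[u] != m2) {
            mark[u] = m2;
            side_b.push_back(u);
          }
        }
        if (joined) break;
      } else {
        winner = &side_b;
        break;
      }
    }
    if (joined) {
      intra_sign(c, +1.0);
      return;
    }
    // split: move the finished (smaller) side into a new component
    int nc;
    if (!comp_spare.empty()) {
      nc = comp_spare.back();
      comp_spare.pop_back();
      comp_alive[nc] = 1;
      comp_members[nc].clear();
      std::fill(comp_free[nc].begin(), comp_free[nc].end(), 0);
    } else {
      nc = comp_members.size();
      comp_members.push_back({});
      comp_free.push_back(std::vector<long long>(Ffree.size(), 0));
      comp_alive.push_back(1);
    }
    auto& old_mem = comp_members[c];
    for (int v : *winner) {
      // O(1) removal from the old member list via position index
      int p = inst_mpos[v];
      int last = old_mem.back();
      old_mem[p] = last;
      inst_mpos[last] = p;
      old_mem.pop_back();
      comp_of[v] = nc;
      inst_mpos[v] = comp_members[nc].size();
      comp_members[nc].push_back(v);
      for (int s : inst_slots[v])
        if (slot_bond[s] == -1) {
          comp_free[nc][slot_class[s]]++;
          comp_free[c][slot_class[s]]--;
        }
    }
    intra_sign(c, +1.0);
    intra_sign(nc, +1.0);
  }

  // sample an eligible ordered free-site pair for rule r and bind it
  void do_assoc(int r) {
    int ca = rule_a[r], cb = rule_b[r];
    int s1 = -1, s2 = -1;
    for (int attempt = 0; attempt < 200; ++attempt) {
      int a, b;
      if (ca == cb) {
        int i = rint(Ffree[ca]), j = rint(Ffree[ca]);
        if (i == j) continue;
        a = free_pool[ca][i];
        b = free_pool[ca][j];
      } else {
        a = free_pool[ca][rint(Ffree[ca])];
        b = free_pool[cb][rint(Ffree[cb])];
      }
      if (!allow_intra && comp_of[slot_inst[a]] == comp_of[slot_inst[b]]) continue;
      s1 = a;
      s2 = b;
      break;
    }
    if (s1 < 0) {  // exact fallback: index uniformly into the eligible pairs
      double pairs = assoc_pairs(r);
      if (pairs <= 0) return;  // stale propensity; no eligible pair
      long long k = (long long)(runif01() * pairs);
      if (ca != cb) {
        for (int a : free_pool[ca]) {
          long long partners =
              Ffree[cb] - (allow_intra ? 0 : comp_free[comp_of[slot_inst[a]]][cb]);
          if (k < partners) {
            int cc = comp_of[slot_inst[a]];
            for (int b : free_pool[cb]) {
              if (!allow_intra && comp_of[slot_inst[b]] == cc) continue;
              if (k == 0) {
                s1 = a;
                s2 = b;
                break;
              }
              --k;
            }
            break;
          }
          k -= partners;
        }
      } else {
        const auto& pool = free_pool[ca];
        int F = pool.size();
        for (int i = 0; i < F && s1 < 0; ++i) {
          int ci = comp_of[slot_inst[pool[i]]];
          for (int j = i + 1; j < F; ++j) {
            if (!allow_intra && comp_of[slot_inst[pool[j]]] == ci) continue;
            if (k == 0) {
              s1 = pool[i];
              s2 = pool[j];
              break;
            }
            --k;
          }
        }
      }
      if (s1 < 0) return;
    }
    // orient: s1 must be the rule's a-side
    if (slot_class[s1] != ca) std::swap(s1, s2);
    make_bond(s1, s2, r);
  }

  // snapshot: canonical key counts of the current complexes
  void snapshot(std::map<std::string, std::vector<std::pair<int, int>>>& acc,
                int snap_idx) {
    std::map<std::string, int> counts;
    std::vector<int> loc(NI, -1);
    for (size_t c = 0; c < comp_members.size(); ++c) {
      if (!comp_alive[c] || comp_members[c].empty()) continue;
      const auto& mem = comp_members[c];
      LGraph g;
      g.n = mem.size();
      for (size_t i = 0; i < mem.size(); ++i) {
        loc[mem[i]] = i;
        g.label.push_back(species_names[inst_species[mem[i]]]);
      }
      for (int v : mem)
        for (int b : inst_bonds[v]) {
          int i1 = slot_inst[bond_s1[b]];
          if (i1 != v) continue;  // add each bond once, from its a-side instance
          int i2 = slot_inst[bond_s2[b]];
          int r = bond_rule[b];
          g.ea.push_back(loc[i1]);
          g.eb.push_back(loc[i2]);
          g.rule.push_back(rule_ids[r]);
          g.sa.push_back(class_site[slot_class[bond_s1[b]]]);
          g.sb.push_back(class_site[slot_class[bond_s2[b]]]);
        }
      counts[component_key(g)] += 1;
    }
    for (const auto& kv : counts) acc[kv.first].push_back({snap_idx, kv.second});
  }

  List run(double t_end, double burn_in, int n_samples) {
    std::vector<double> stimes(n_samples);
    double t0 = burn_in * t_end;
    for (int i = 0; i < n_samples; ++i)
      stimes[i] = t0 + (i + 1) * (t_end - t0) / n_samples;
    std::map<std::string, std::vector<std::pair<int, int>>> acc;
    double t = 0.0;
    int next_s = 0;
    bool absorbed = false;
    std::vector<double> prop(2 * R);
    while (next_s < n_samples) {
      double A = 0.0;
      for (int r = 0; r < R; ++r) {
        prop[r] = kon[r] * assoc_pairs(r);
        prop[R + r] = koff[r] * (double)rule_bonds[r].size();
        A += prop[r] + prop[R + r];
      }
      if (A <= 0.0) {
        absorbed = true;
        while (next_s < n_samples) snapshot(acc, next_s++);
        break;
      }
      double tn = t - std::log(runif01()) / A;
      while (next_s < n_samples && stimes[next_s] <= tn) snapshot(acc, next_s++);
      if (next_s >= n_samples) break;
      t = tn;
      double u = runif01() * A;
      int ev = 2 * R - 1;
      for (int k = 0; k < 2 * R; ++k) {
        if (u < prop[k]) {
          ev = k;
          break;
        }
        u -= prop[k];
      }
      ++n_events;
      if (ev < R) {
        do_assoc(ev);
      } else {
        int r = ev - R;
        if (!rule_bonds[r].empty())
          break_bond(rule_bonds[r][rint(rule_bonds[r].size())]);
      }
    }
    // assemble snapshot count matrix (keys in lexicographic order)
    int K = acc.size();
    CharacterVector keys(K);
    IntegerMatrix m(n_samples, K);
    int j = 0;
    for (const auto& kv : acc) {
      keys[j] = kv.first;
      for (const auto& pr : kv.second) m(pr.first, j) = pr.second;
      ++j;
    }
    return List::create(_["keys"] = keys, _["counts"] = m,
                        _["n_events"] = (double)n_events,
                        _["absorbed"] = absorbed);
  }
};

// [[Rcpp::export]]
List cpp_run_ssa(List cmodel, IntegerVector counts, double t_end, double burn_in,
                 int n_samples, double seed) {
  Engine eng;
  eng.init(cmodel, counts, (uint64_t)seed);
  return eng.run(t_end, burn_in, n_samples);
}

// FNV-1a 64-bit hashes of key strings (hex), used by the complex catalog to
// index arbitrarily long canonical keys.
// [[Rcpp::export]]
CharacterVector cpp_hash_keys(CharacterVector keys) {
  int n = keys.size();
  CharacterVector out(n);
  char buf[17];
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(keys, i));
    uint64_t h = 14695981039346656037ull;
    for (const char* p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= 1099511628211ull;
    }
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}
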