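#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Rejection-sampling core of the reaction-system generator: reactions are
// built by randomly splitting and recombining molecules, so atom-wise mass
// conservation holds by construction. Uses R's RNG throughout, so results
// are reproducible from set.seed().

namespace {

typedef std::vector<int> Comp;

struct Ctx {
  int n_species, n_groups, max_mol_size;
  std::vector<int> species_group;            // 1..G per species
  std::vector<Comp> comp;                    // molecule compositions
  std::vector<int> scope;                    // 0 = mixed/global, else group
  std::vector<std::vector<int> > group_mols; // indices per group (0-based)
  std::unordered_map<std::string, int> mol_hash;
  std::unordered_set<std::string> rxn_hash;
  // accepted reactions (0-based molecule indices)
  std::vector<std::vector<int> > sub_idx, sub_mult, prod_idx, prod_mult;
  std::vector<int> locality;                 // 0 = bridge
};

int runi(int n) {  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

std::string comp_key(const Comp& c) {
  std::string s;
  s.reserve(c.size());
  for (size_t i = 0; i < c.size(); ++i) s.push_back((char)(c[i] + 1));
  return s;
}

int comp_scope(const Comp& c, const std::vector<int>& species_group) {
  int g = 0;
  for (size_t i = 0; i < c.size(); ++i) {
    if (c[i] > 0) {
      if (g == 0) g = species_group[i];
      else if (g != species_group[i]) return 0;
    }
  }
  return g;
}

// registers a composition, returns its 0-based index
int register_molecule(Ctx& ctx, const Comp& c) {
  std::string key = comp_key(c);
  std::unordered_map<std::string, int>::iterator it = ctx.mol_hash.find(key);
  if (it != ctx.mol_hash.end()) return it->second;
  int idx = (int)ctx.comp.size();
  ctx.comp.push_back(c);
  int sc = comp_scope(c, ctx.species_group);
  ctx.scope.push_back(sc);
  if (sc > 0) ctx.group_mols[sc - 1].push_back(idx);
  ctx.mol_hash[key] = idx;
  return idx;
}

std::string side_key(const std::vector<int>& idx, const std::vector<int>& mult) {
  std::vector<std::pair<int, int> > v;
  for (size_t i = 0; i < idx.size(); ++i)
    v.push_back(std::make_pair(idx[i], mult[i]));
  std::sort(v.begin(), v.end());
  std::string s;
  for (size_t i = 0; i < v.size(); ++i) {
    s += std::to_string(v[i].first);
    s.push_back('x');
    s += std::to_string(v[i].second);
    s.push_back('+');
  }
  return s;
}

std::string reaction_key_cpp(const std::vector<int>& si, const std::vector<int>& sm,
                             const std::vector<int>& pi, const std::vector<int>& pm) {
  std::string a = side_key(si, sm), b = side_key(pi, pm);
  if (b < a) std::swap(a, b);
  return a + "=" + b;
}

// one attempt; returns true and fills the reaction on success
bool attempt(Ctx& ctx, int locality, bool allow_new,
             std::vector<int>& sub, std::vector<int>& sub_mult,
             std::vector<int>& prod, std::vector<int>& prod_mult,
             std::string& key) {
  sub.clear(); sub_mult.clear(); prod.clear(); prod_mult.clear();
  const bool bridge = locality == 0;
  if (bridge) {
    int g1 = runi(ctx.n_groups);
    int g2 = runi(ctx.n_groups - 1);
    if (g2 >= g1) ++g2;
    const std::vector<int>* p1 = &ctx.group_mols[g1];
    const std::vector<int>* p2 = &ctx.group_mols[g2];
    if (p1->empty() || p2->empty()) return false;
    sub.push_back((*p1)[runi((int)p1->size())]);
    sub.push_back((*p2)[runi((int)p2->size())]);
    sub_mult.push_back(1 + runi(2));
    sub_mult.push_back(1 + runi(2));
  } else {
    const std::vector<int>& pool = ctx.group_mols[locality - 1];
    if (pool.empty()) return false;
    int ns = 1 + runi(2);
    for (int i = 0; i < ns; ++i) {
      sub.push_back(pool[runi((int)pool.size())]);
      sub_mult.push_back(1 + runi(2));
    }
  }
  if (sub.size() == 2 && sub[0] == sub[1]) {
    sub_mult[0] += sub_mult[1];
    sub.pop_back(); sub_mult.pop_back();
  }

  // pool the substrate atoms
  std::vector<int> atoms;
  for (size_t i = 0; i < sub.size(); ++i) {
    const Comp& c = ctx.comp[sub[i]];
    for (int s = 0; s < ctx.n_species; ++s)
      for (int k = 0; k < c[s] * sub_mult[i]; ++k) atoms.push_back(s);
  }
  int total = (int)atoms.size();
  int npart = 1 + runi(3);
  if (npart > total) npart = total;

  // shuffle and cut into npart non-empty parts
  for (int i = total - 1; i > 0; --i) {
    int j = runi(i + 1);
    std::swap(atoms[i], atoms[j]);
  }
  int cuts[2] = {0, 0};
  if (npart >= 2) {
    cuts[0] = 1 + runi(total - 1);
    if (npart == 3) {
      do { cuts[1] = 1 + runi(total - 1); } while (cuts[1] == cuts[0]);
      if (cuts[1] < cuts[0]) std::swap(cuts[0], cuts[1]);
    }
  }

  std::vector<Comp> parts;
  std::vector<std::string> part_keys;
  std::vector<int> part_idx;           // matched molecule index or -1
  int lo = 0;
  for (int p = 0; p < npart; ++p) {
    int hi = (p == npart - 1) ? total : cuts[p];
    if (hi - lo > ctx.max_mol_size) return false;
    Comp c(ctx.n_species, 0);
    for (int i = lo; i < hi; ++i) c[atoms[i]]++;
    lo = hi;
    std::string k = comp_key(c);
    // merge identical parts into multiplicity
    bool merged = false;
    for (size_t q = 0; q < part_keys.size(); ++q) {
      if (part_keys[q] == k) { prod_mult[q]++; merged = true; break; }
    }
    if (merged) continue;
    std::unordered_map<std::string, int>::iterator it = ctx.mol_hash.find(k);
    int idx = (it == ctx.mol_hash.end()) ? -1 : it->second;
    if (idx < 0 && !allow_new) return false;
    // disjointness with substrates
    if (idx >= 0)
      for (size_t q = 0; q < sub.size(); ++q)
        if (sub[q] == idx) return false;
    parts.push_back(c);
    part_keys.push_back(k);
    part_idx.push_back(idx);
    prod_mult.push_back(1);
  }

  if (bridge) {
    bool ok = false;
    for (size_t i = 0; i < sub.size() && !ok; ++i) {
      int ss = ctx.scope[sub[i]];
      if (ss == 0) continue;
      for (size_t p = 0; p < parts.size(); ++p) {
        int ps = comp_scope(parts[p], ctx.species_group);
        if (ps > 0 && ps != ss) { ok = true; break; }
      }
    }
    if (!ok) return false;
  }

  // provisional indices for new molecules
  int next_new = (int)ctx.comp.size();
  prod.resize(parts.size());
  for (size_t p = 0; p < parts.size(); ++p)
    prod[p] = part_idx[p] >= 0 ? part_idx[p] : next_new++;

  key = reaction_key_cpp(sub, sub_mult, prod, prod_mult);
  if (ctx.rxn_hash.count(key)) return false;

  for (size_t p = 0; p < parts.size(); ++p) {
    if (part_idx[p] < 0) {
      int idx = register_molecule(ctx, parts[p]);
      if (idx != prod[p]) return false;  // defensive; cannot happen
    }
  }
  return true;
}

}  // namespace

// Generate reactions of the requested locality classes (0 = bridge, else a
// group id) on top of an existing set of molecules and reactions (the latter
// enter only the duplicate-reaction hash). Returns all molecules (existing +
// new) and the newly generated reactions with 1-based molecule indices.
// [[Rcpp::export]]
List generate_core_cpp(IntegerMatrix comp0, IntegerVector species_group,
                       int n_groups, List rxn0,
                       IntegerVector localities, int seed_per_group,
                       int max_tries, int max_mol_size) {
  Ctx ctx;
  ctx.n_species = comp0.ncol();
  ctx.n_groups = n_groups;
  ctx.max_mol_size = max_mol_size;
  ctx.species_group.assign(species_group.begin(), species_group.end());
  ctx.group_mols.resize(n_groups);
  for (int i = 0; i < comp0.nrow(); ++i) {
    Comp c(ctx.n_species);
    for (int s = 0; s < ctx.n_species; ++s) c[s] = comp0(i, s);
    register_molecule(ctx, c);
  }
  // existing reactions seed the duplicate hash
  for (int r = 0; r < rxn0.size(); ++r) {
    List rr = rxn0[r];
    IntegerVector si = rr[0], sm = rr[1], pi = rr[2], pm = rr[3];
    std::vector<int> vsi(si.begin(), si.end()), vsm(sm.begin(), sm.end());
    std::vector<int> vpi(pi.begin(), pi.end()), vpm(pm.begin(), pm.end());
    for (size_t i = 0; i < vsi.size(); ++i) vsi[i] -= 1;
    for (size_t i = 0; i < vpi.size(); ++i) vpi[i] -= 1;
    ctx.rxn_hash.insert(reaction_key_cpp(vsi, vsm, vpi, vpm));
  }

  if (seed_per_group > 0) {
    for (int g = 1; g <= n_groups; ++g) {
      std::vector<int> pool;
      for (int s = 0; s < ctx.n_species; ++s)
        if (ctx.species_group[s] == g) pool.push_back(s);
      for (int i = 0; i < seed_per_group; ++i) {
        int size = 1 + runi(max_mol_size);
        Comp c(ctx.n_species, 0);
        for (int k = 0; k < size; ++k) c[pool[runi((int)pool.size())]]++;
        register_molecule(ctx, c);
      }
    }
  }

  std::vector<int> sub, sub_mult, prod, prod_mult;
  std::string key;
  for (int q = 0; q < localities.size(); ++q) {
    int loc = localities[q];
    bool done = false;
    for (int phase = 0; phase < 2 && !done; ++phase) {
      for (int t = 0; t < max_tries; ++t) {
        if (attempt(ctx, loc, phase == 1, sub, sub_mult, prod, prod_mult, key)) {
          ctx.sub_idx.push_back(sub);
          ctx.sub_mult.push_back(sub_mult);
          ctx.prod_idx.push_back(prod);
          ctx.prod_mult.push_back(prod_mult);
          ctx.locality.push_back(loc);
          ctx.rxn_hash.insert(key);
          done = true;
          break;
        }
      }
    }
    if (!done) {
      return List::create(_["ok"] = false, _["failed_locality"] = loc);
    }
  }

  int n_mol = (int)ctx.comp.size();
  IntegerMatrix comp(n_mol, ctx.n_species);
  IntegerVector scope(n_mol);
  for (int i = 0; i < n_mol; ++i) {
    for (int s = 0; s < ctx.n_species; ++s) comp(i, s) = ctx.comp[i][s];
    scope[i] = ctx.scope[i] == 0 ? NA_INTEGER : ctx.scope[i];
  }
  int n_new = (int)ctx.sub_idx.size();
  List rsub(n_new), rsubm(n_new), rprod(n_new), rprodm(n_new);
  IntegerVector rloc(n_new);
  for (int r = 0; r < n_new; ++r) {
    IntegerVector si(ctx.sub_idx[r].begin(), ctx.sub_idx[r].end());
    IntegerVector pi(ctx.prod_idx[r].begin(), ctx.prod_idx[r].end());
    for (int i = 0; i < si.size(); ++i) si[i] += 1;
    for (int i = 0; i < pi.size(); ++i) pi[i] += 1;
    rsub[r] = si;
    rsubm[r] = IntegerVector(ctx.sub_mult[r].begin(), ctx.sub_mult[r].end());
    rprod[r] = pi;
    rprodm[r] = IntegerVector(ctx.prod_mult[r].begin(), ctx.prod_mult[r].end());
    rloc[r] = ctx.locality[r] == 0 ? NA_INTEGER : ctx.locality[r];
  }
  return List::create(
    _["ok"] = true,
    _["comp"] = comp, _["scope"] = scope,
    _["sub_idx"] = rsub, _["sub_mult"] = rsubm,
    _["prod_idx"] = rprod, _["prod_mult"] = rprodm,
    _["locality"] = rloc);
}
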