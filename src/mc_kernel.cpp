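#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Metropolis kernel for the counterion-bridging toy model.
//
// Particles carry S negative unit-charge sites each and live in a periodic
// box (2-D membrane plane by default, 3-D optional). Divalent ions diffuse
// in the same box and may occupy sites of particles within contact_radius;
// a site has two coordination slots (a carboxylate offers two oxygens;
// the second ion on a neutralized site is the overcharging step, priced
// separately by b2). Energy (units kT):
//   E = b  * n_first_bonds + b2 * n_second_bonds
//     + g  * sum_ions max(0, distinct_particles(ion) - 1)     (bridging)
//     + c  * [ sum_complexes q^2 / sqrt(m)  +  4 * n_unbound ] (charging)
// where a complex is a connected component of m particles linked by shared
// ions and q = 2 * (ions bound in complex) - S * m; q^2/sqrt(m) is the
// Coulomb self-energy scaling of a compact 2-D cluster, which makes
// overcharge at fixed surface density superextensive and caps cluster
// growth at high ion load.
// Bound pairs further than contact_radius are forbidden (hard constraint),
// so displacement moves that would stretch a bond are rejected.
//
// Proposals: per sweep, one displacement attempt per particle and per ion,
// plus 4 * n_sites bind/unbind/replace attempts. Each attempt
// draws a uniform (ion, site) pair and a fair action coin:
//   coin 1 - toggle: unbind if the ion occupies the site, else bind into a
//            free slot;
//   coin 2 - replace: swap a uniformly chosen resident ion for the drawn
//            one. The reverse replace has identical proposal probability
//            and is always feasible, so Metropolis acceptance on the total
//            energy keeps detailed balance; replacement removes the
//            kinetic trap of saturated sites blocking bridge formation.

struct Model {
  int np, S, ni, ndim, max_sites;
  bool allow_bridging;
  double b, b2, g, c, R;
  std::vector<double> box;
  std::vector<double> px;  // np*ndim
  std::vector<double> ix;  // ni*ndim
  std::vector<int> occ;    // 2 slots per site -> ion or -1
  std::vector<int> ion_nb; // bonds per ion

  double wrap(double d, double L) const { return d - L * std::round(d / L); }

  double dist_ip(int u, int p) const {
    double s = 0;
    for (int k = 0; k < ndim; ++k) {
      double d = wrap(ix[u * ndim + k] - px[p * ndim + k], box[k]);
      s += d * d;
    }
    return std::sqrt(s);
  }

  int n_on_site(int s) const {
    return (occ[2 * s] >= 0) + (occ[2 * s + 1] >= 0);
  }

  // O(slots) total energy: iterate occupied slots, group (ion, particle)
  // incidences by ion, then union-find over particles.
  double energy() const {
    int nb1 = 0, nb2 = 0;
    std::vector<std::pair<int, int>> inc;   // (ion, particle)
    inc.reserve(2 * np * S);
    for (int s = 0; s < np * S; ++s) {
      int n_here = 0;
      for (int slot = 0; slot < 2; ++slot) {
        int u = occ[2 * s + slot];
        if (u < 0) continue;
        ++n_here;
        if (n_here == 1) ++nb1; else ++nb2;
        inc.push_back(std::make_pair(u, s / S));
      }
    }
    double e = b * (double)nb1 + b2 * (double)nb2;
    std::sort(inc.begin(), inc.end());
    inc.erase(std::unique(inc.begin(), inc.end()), inc.end());
    std::vector<int> par(np);
    for (int p = 0; p < np; ++p) par[p] = p;
    int n_bound_ions = 0;
    std::vector<std::pair<int, int>> ion_first; // (ion, first particle)
    for (size_t k = 0; k < inc.size();) {
      int u = inc[k].first;
      size_t k0 = k;
      while (k < inc.size() && inc[k].first == u) ++k;
      int deg = (int)(k - k0);
      ++n_bound_ions;
      ion_first.push_back(std::make_pair(u, inc[k0].second));
      if (deg > 1) {
        e += g * (double)(deg - 1);
        int r0 = -1;
        for (size_t j = k0; j < k; ++j) {
          int x = inc[j].second;
          while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
          if (r0 < 0) r0 = x; else if (x != r0) par[x] = r0;
        }
      }
    }
    std::vector<int> comp_np(np, 0), comp_ni(np, 0);
    for (int p = 0; p < np; ++p) {
      int x = p;
      while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
      comp_np[x] += 1;
    }
    for (size_t k = 0; k < ion_first.size(); ++k) {
      int x = ion_first[k].second;
      while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
      comp_ni[x] += 1;
    }
    // Complex self-energy: q^2 / sqrt(m) mimics the unscreened Coulomb
    // self-energy of a compact 2-D cluster of m particles (radius ~ sqrt(m)),
    // so overcharge at fixed surface density is superextensive and caps
    // cluster growth; an unbound ion is its own complex (q = 2, m -> 1/4
    // effective size, i.e. weight 4).
    double echg = 4.0 * (double)(ni - n_bound_ions);
    for (int p = 0; p < np; ++p) {
      if (comp_np[p] == 0) continue;
      double q = 2.0 * comp_ni[p] - (double)S * comp_np[p];
      echg += q * q / std::sqrt((double)comp_np[p]);
    }
    return e + c * echg;
  }

  void components(std::vector<int>& comp_of) const {
    std::vector<int> par(np);
    for (int p = 0; p < np; ++p) par[p] = p;
    for (int u = 0; u < ni; ++u) {
      int first = -1;
      for (int s = 0; s < 2 * np * S; ++s) {
        if (occ[s] != u) continue;
        int p = (s / 2) / S;
        if (first < 0) { first = p; continue; }
        int a = first, bb = p;
        while (par[a] != a) { par[a] = par[par[a]]; a = par[a]; }
        while (par[bb] != bb) { par[bb] = par[par[bb]]; bb = par[bb]; }
        if (a != bb) par[bb] = a;
      }
    }
    comp_of.resize(np);
    for (int p = 0; p < np; ++p) {
      int x = p;
      while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
      comp_of[p] = x;
    }
  }

  // particle of first bound site of ion u, or -1
  int ion_particle(int u) const {
    if (ion_nb[u] == 0) return -1;
    for (int s = 0; s < 2 * np * S; ++s)
      if (occ[s] == u) return (s / 2) / S;
    return -1;
  }

  bool ion_bond_ok(int u) const {
    if (ion_nb[u] == 0) return true;
    for (int s = 0; s < 2 * np * S; ++s)
      if (occ[s] == u && dist_ip(u, (s / 2) / S) > R) return false;
    return true;
  }
};

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(int np, int S, int ni, int ndim, NumericVector box,
                NumericMatrix p0, NumericMatrix i0,
                double bind_e, double second_bind_e, double bridge_e,
                double charge_c, double contact_radius, int max_sites,
                double step_particle, double step_ion,
                int n_sweeps, int sample_every, bool allow_bridging) {
  Model m;
  m.np = np; m.S = S; m.ni = ni; m.ndim = ndim; m.max_sites = max_sites;
  m.b = bind_e; m.b2 = second_bind_e; m.g = bridge_e; m.c = charge_c;
  m.R = contact_radius;
  m.allow_bridging = allow_bridging;
  m.box.assign(box.begin(), box.begin() + ndim);
  m.px.resize(np * ndim); m.ix.resize(std::max(ni, 1) * ndim);
  for (int p = 0; p < np; ++p)
    for (int k = 0; k < ndim; ++k) m.px[p * ndim + k] = p0(p, k);
  for (int u = 0; u < ni; ++u)
    for (int k = 0; k < ndim; ++k) m.ix[u * ndim + k] = i0(u, k);
  m.occ.assign(2 * np * S, -1);
  m.ion_nb.assign(std::max(ni, 1), 0);

  double E = m.energy();
  const int n_samples = (sample_every > 0) ? (n_sweeps / sample_every) : 0;
  NumericMatrix obs(n_samples, 5);
  int si = 0;
  double acc_p = 0, try_p = 0, acc_i = 0, try_i = 0, acc_b = 0, try_b = 0;
  int n_bind_prop = 4 * np * S;   // fixed per sweep; independent of ion count

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int p = 0; p < np && step_particle > 0; ++p) {
      try_p += 1;
      std::vector<double> old(m.px.begin() + p * ndim,
                              m.px.begin() + (p + 1) * ndim);
      for (int k = 0; k < ndim; ++k) {
        double x = m.px[p * ndim + k] +
          (unif_rand() * 2.0 - 1.0) * step_particle;
        x -= m.box[k] * std::floor(x / m.box[k]);
        m.px[p * ndim + k] = x;
      }
      bool ok = true;
      for (int s = 2 * p * S; s < 2 * (p + 1) * S && ok; ++s) {
        int u = m.occ[s];
        if (u >= 0 && m.dist_ip(u, p) > m.R) ok = false;
      }
      if (ok) acc_p += 1;
      else for (int k = 0; k < ndim; ++k) m.px[p * ndim + k] = old[k];
    }
    for (int u = 0; u < ni && step_ion > 0; ++u) {
      try_i += 1;
      std::vector<double> old(m.ix.begin() + u * ndim,
                              m.ix.begin() + (u + 1) * ndim);
      for (int k = 0; k < ndim; ++k) {
        double x = m.ix[u * ndim + k] + (unif_rand() * 2.0 - 1.0) * step_ion;
        x -= m.box[k] * std::floor(x / m.box[k]);
        m.ix[u * ndim + k] = x;
      }
      if (m.ion_bond_ok(u)) acc_i += 1;
      else for (int k = 0; k < ndim; ++k) m.ix[u * ndim + k] = old[k];
    }
    for (int t = 0; t < n_bind_prop && ni > 0; ++t) {
      int u = (int)(unif_rand() * ni); if (u == ni) --u;
      int s = (int)(unif_rand() * (np * S)); if (s == np * S) --s;
      bool coin_toggle = unif_rand() < 0.5;
      int slot_of_u = -1;
      if (m.occ[2 * s] == u) slot_of_u = 2 * s;
      else if (m.occ[2 * s + 1] == u) slot_of_u = 2 * s + 1;
      if (coin_toggle) {
        if (slot_of_u >= 0) {                                   // unbind
          try_b += 1;
          m.occ[slot_of_u] = -1; m.ion_nb[u] -= 1;
          double Enew = m.energy();
          if (Enew <= E || unif_rand() < std::exp(-(Enew - E))) {
            E = Enew; acc_b += 1;
          } else { m.occ[slot_of_u] = u; m.ion_nb[u] += 1; }
        } else if (m.n_on_site(s) < 2 && m.ion_nb[u] < m.max_sites &&
                   m.dist_ip(u, s / S) <= m.R &&
                   (m.allow_bridging || m.ion_nb[u] == 0 ||
                    m.ion_particle(u) == s / S)) {              // bind
          try_b += 1;
          int slot = (m.occ[2 * s] < 0) ? 2 * s : 2 * s + 1;
          m.occ[slot] = u; m.ion_nb[u] += 1;
          double Enew = m.energy();
          if (Enew <= E || unif_rand() < std::exp(-(Enew - E))) {
            E = Enew; acc_b += 1;
          } else { m.occ[slot] = -1; m.ion_nb[u] -= 1; }
        }
      } else {
        // replace a uniformly chosen resident (not u) by u
        if (slot_of_u >= 0 || m.n_on_site(s) == 0) continue;
        if (m.ion_nb[u] >= m.max_sites || m.dist_ip(u, s / S) > m.R) continue;
        if (!m.allow_bridging && m.ion_nb[u] > 0 &&
            m.ion_particle(u) != s / S) continue;
        int slots[2], nres = 0;
        for (int sl = 0; sl < 2; ++sl)
          if (m.occ[2 * s + sl] >= 0) slots[nres++] = 2 * s + sl;
        int pick = slots[0];
        if (nres == 2) {
          pick = (unif_rand() < 0.5) ? slots[0] : slots[1];
        }
        int v = m.occ[pick];
        try_b += 1;
        m.occ[pick] = u; m.ion_nb[u] += 1; m.ion_nb[v] -= 1;
        double Enew = m.energy();
        if (Enew <= E || unif_rand() < std::exp(-(Enew - E))) {
          E = Enew; acc_b += 1;
        } else { m.occ[pick] = v; m.ion_nb[u] -= 1; m.ion_nb[v] += 1; }
      }
    }
    if (sample_every > 0 && sweep % sample_every == 0 && si < n_samples) {
      std::vector<int> comp;
      m.components(comp);
      std::vector<int> size(np, 0);
      for (int p = 0; p < np; ++p) size[comp[p]] += 1;
      int largest = 0, ncomp = 0;
      for (int p = 0; p < np; ++p) {
        if (size[p] > largest) largest = size[p];
        if (size[p] > 0) ++ncomp;
      }
      int n_bound = 0;
      for (int s = 0; s < 2 * np * S; ++s) if (m.occ[s] >= 0) ++n_bound;
      obs(si, 0) = sweep; obs(si, 1) = E; obs(si, 2) = n_bound;
      obs(si, 3) = largest;
      obs(si, 4) = (double)np / (double)std::max(ncomp, 1);
      ++si;
    }
  }

  NumericMatrix pfin(np, ndim), ifin(std::max(ni, 1), ndim);
  for (int p = 0; p < np; ++p)
    for (int k = 0; k < ndim; ++k) pfin(p, k) = m.px[p * ndim + k];
  for (int u = 0; u < ni; ++u)
    for (int k = 0; k < ndim; ++k) ifin(u, k) = m.ix[u * ndim + k];
  IntegerMatrix sb(np * S, 2);
  for (int s = 0; s < np * S; ++s)
    for (int sl = 0; sl < 2; ++sl)
      sb(s, sl) = (m.occ[2 * s + sl] >= 0) ? m.occ[2 * s + sl] + 1 : NA_INTEGER;

  return List::create(
    _["observables"] = obs,
    _["particle_xy"] = pfin,
    _["ion_xy"] = ifin,
    _["site_bond"] = sb,
    _["energy_running"] = E,
    _["energy_recomputed"] = m.energy(),
    _["acceptance"] = NumericVector::create(
      _["particle"] = try_p > 0 ? acc_p / try_p : NA_REAL,
      _["ion"] = try_i > 0 ? acc_i / try_i : NA_REAL,
      _["bind"] = try_b > 0 ? acc_b / try_b : NA_REAL));
}
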