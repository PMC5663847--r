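#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Continuous-time multi-deme coalescent with piecewise-constant sizes.
// Sizes are passed as effective gene-copy numbers C (pair coalescence rate
// 1/C per generation), so the R side owns ploidy scaling (2N nuclear, N/2
// mtDNA). Demes exchange lineages only at merge/admixture events; there is
// no migration during divergence.

static double deme_size_at(const std::vector<double> &times,
                           const std::vector<double> &vals, double t) {
  // last piece with start time <= t
  size_t i = times.size() - 1;
  while (i > 0 && times[i] > t) --i;
  return vals[i];
}

// [[Rcpp::export]]
List sample_genealogy_cpp(IntegerVector samples, List size_times,
                          List size_vals, NumericVector ev_time,
                          IntegerVector ev_type, IntegerVector ev_from,
                          IntegerVector ev_to, IntegerVector ev_to2,
                          NumericVector ev_prob) {
  const int n_demes = samples.size();
  int n_tip = 0;
  for (int d = 0; d < n_demes; ++d) n_tip += samples[d];
  if (n_tip < 1) stop("no samples");
  const int n_nodes = 2 * n_tip - 1;

  std::vector<std::vector<double> > st(n_demes), sv(n_demes);
  for (int d = 0; d < n_demes; ++d) {
    st[d] = as<std::vector<double> >(size_times[d]);
    sv[d] = as<std::vector<double> >(size_vals[d]);
  }

  std::vector<int> parent(n_nodes, -1);
  std::vector<double> ntime(n_nodes, 0.0);
  std::vector<std::vector<int> > active(n_demes);
  int id = 0;
  for (int d = 0; d < n_demes; ++d)
    for (int i = 0; i < samples[d]; ++i) active[d].push_back(id++);
  int next_node = n_tip;

  // global breakpoints: size-change times and event times
  std::vector<double> bp;
  for (int d = 0; d < n_demes; ++d)
    for (size_t i = 1; i < st[d].size(); ++i) bp.push_back(st[d][i]);
  for (int e = 0; e < ev_time.size(); ++e) bp.push_back(ev_time[e]);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

  int n_active = n_tip;
  double t = 0.0;
  size_t next_ev = 0;

  for (size_t b = 0; b <= bp.size(); ++b) {
    double t_end = (b < bp.size()) ? bp[b] : R_PosInf;
    // coalesce within each deme until t_end
    for (int d = 0; d < n_demes && n_active > 1; ++d) {
      double td = t;
      while (active[d].size() >= 2) {
        int k = active[d].size();
        double C = deme_size_at(st[d], sv[d], td);
        if (C <= 0) stop("non-positive deme size");
        double rate = 0.5 * k * (k - 1) / C;
        double dt = R::rexp(1.0 / rate);
        if (td + dt >= t_end) break;
        td += dt;
        int i = (int)(R::unif_rand() * k);
        int j = (int)(R::unif_rand() * (k - 1));
        if (j >= i) ++j;
        int ni = active[d][i], nj = active[d][j];
        int node = next_node++;
        parent[ni] = node;
        parent[nj] = node;
        ntime[node] = td;
        if (i > j) std::swap(i, j);
        active[d][i] = node;
        active[d].erase(active[d].begin() + j);
        --n_active;
      }
    }
    if (n_active == 1) break;
    if (b == bp.size()) break;
    t = t_end;
    // apply events scheduled at this breakpoint
    while (next_ev < (size_t)ev_time.size() && ev_time[next_ev] <= t) {
      int from = ev_from[next_ev] - 1, to = ev_to[next_ev] - 1;
      if (ev_type[next_ev] == 0) {  // merge
        for (size_t i = 0; i < active[from].size(); ++i)
          active[to].push_back(active[from][i]);
        active[from].clear();
      } else {  // admixture: each lineage to `to` w.p. prob, else `to2`
        int to2 = ev_to2[next_ev] - 1;
        double p = ev_prob[next_ev];
        for (size_t i = 0; i < active[from].size(); ++i) {
          if (R::unif_rand() < p)
            active[to].push_back(active[from][i]);
          else
            active[to2].push_back(active[from][i]);
        }
        active[from].clear();
      }
      ++next_ev;
    }
  }

  if (n_active > 1) {
    int occupied = 0;
    for (int d = 0; d < n_demes; ++d)
      if (!active[d].empty()) ++occupied;
    if (occupied > 1) stop("lineages stranded: demography has no single root");
    stop("internal error: unfinished coalescent in root deme");
  }

  return List::create(_["parent"] = wrap(parent), _["time"] = wrap(ntime),
                      _["n_tip"] = n_tip);
}

// nodes in decreasing time order (parents before children); tips last
static std::vector<int> preorder_by_time(const std::vector<double> &ntime,
                                         int n_nodes) {
  std::vector<int> ord(n_nodes);
  for (int i = 0; i < n_nodes; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return ntime[a] > ntime[b];
  });
  return ord;
}

// Generalized stepwise mutation on a genealogy: Poisson mutations per
// branch, step size 1 + Geometric(1 - p_gsm), direction symmetric,
// reflecting boundaries on the contiguous state space [0, range - 1].
// [[Rcpp::export]]
IntegerVector mutate_microsat_cpp(IntegerVector parent, NumericVector time,
                                  int n_tip, double mu, double p_gsm,
                                  int range) {
  const int n_nodes = parent.size();
  std::vector<double> nt = as<std::vector<double> >(time);
  std::vector<int> state(n_nodes, range / 2);
  std::vector<int> ord = preorder_by_time(nt, n_nodes);
  for (int oi = 0; oi < n_nodes; ++oi) {
    int v = ord[oi];
    if (parent[v] < 0) continue;  // root keeps midpoint state
    double len = nt[parent[v]] - nt[v];
    int s = state[parent[v]];
    if (mu > 0 && len > 0) {
      int nm = (int)R::rpois(mu * len);
      for (int m = 0; m < nm; ++m) {
        int step = 1;
        if (p_gsm > 0) step += (int)R::rgeom(1.0 - p_gsm);
        if (R::unif_rand() < 0.5) step = -step;
        s += step;
        while (s < 0 || s > range - 1) {  // reflect
          if (s < 0) s = -s;
          if (s > range - 1) s = 2 * (range - 1) - s;
        }
      }
    }
    state[v] = s;
  }
  IntegerVector out(n_tip);
  for (int i = 0; i < n_tip; ++i) out[i] = state[i];
  return out;
}

// Finite-sites sequence mutation with transition/transversion weighting
// kappa:1:1. Returns only sites hit by >= 1 mutation (positions 1-based)
// and the tip states at those sites (0=A,1=C,2=G,3=T); unmutated sites are
// identical across tips and share the root base.
// [[Rcpp::export]]
List mutate_sequence_cpp(IntegerVector parent, NumericVector time, int n_tip,
                         double mu_site, int L, double kappa) {
  const int n_nodes = parent.size();
  std::vector<double> nt = as<std::vector<double> >(time);
  // draw mutation count over the whole tree, assign to branches by length
  std::vector<double> blen(n_nodes, 0.0);
  double total = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] >= 0) {
      blen[v] = nt[parent[v]] - nt[v];
      total += blen[v];
    }
  }
  int n_mut = (total > 0 && mu_site > 0)
                  ? (int)R::rpois(mu_site * (double)L * total)
                  : 0;
  std::vector<double> cum(n_nodes, 0.0);
  double acc = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    acc += blen[v];
    cum[v] = acc;
  }
  std::vector<int> m_node(n_mut), m_site(n_mut);
  std::vector<double> m_when(n_mut);  // time coordinate on the branch
  for (int m = 0; m < n_mut; ++m) {
    double u = R::unif_rand() * total;
    int v = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (v >= n_nodes) v = n_nodes - 1;
    m_node[m] = v;
    m_site[m] = (int)(R::unif_rand() * L);
    if (m_site[m] >= L) m_site[m] = L - 1;
    m_when[m] = nt[v] + R::unif_rand() * blen[v];
  }
  // unique sites
  std::vector<int> sites(m_site);
  std::sort(sites.begin(), sites.end());
  sites.erase(std::unique(sites.begin(), sites.end()), sites.end());
  const int S = sites.size();
  std::vector<int> site_col(L, -1);
  for (int s = 0; s < S; ++s) site_col[sites[s]] = s;

  // per-node mutation lists
  std::vector<std::vector<int> > muts(n_nodes);
  for (int m = 0; m < n_mut; ++m) muts[m_node[m]].push_back(m);

  IntegerMatrix states(n_nodes, S);
  IntegerVector root_base(S);
  std::vector<int> ord = preorder_by_time(nt, n_nodes);
  const int trs[4] = {2, 3, 0, 1};  // transition partner A<->G, C<->T
  for (int oi = 0; oi < n_nodes; ++oi) {
    int v = ord[oi];
    if (parent[v] < 0) {
      for (int s = 0; s < S; ++s) {
        states(v, s) = (int)(R::unif_rand() * 4) & 3;
        root_base[s] = states(v, s);
      }
    } else {
      for (int s = 0; s < S; ++s) states(v, s) = states(parent[v], s);
    }
    // apply this branch's mutations, oldest (largest time) first
    std::vector<int> &mv = muts[v];
    std::sort(mv.begin(), mv.end(), [&](int a, int b) {
      return m_when[a] > m_when[b];
    });
    for (size_t k = 0; k < mv.size(); ++k) {
      int col = site_col[m_site[mv[k]]];
      int b = states(v, col);
      double u = R::unif_rand() * (kappa + 2.0);
      int nb;
      if (u < kappa) {
        nb = trs[b];
      } else {  // one of the two transversions
        int tv1, tv2;
        if (b == 0 || b == 2) { tv1 = 1; tv2 = 3; }
        else { tv1 = 0; tv2 = 2; }
        nb = (u - kappa < 1.0) ? tv1 : tv2;
      }
      states(v, col) = nb;
    }
  }
  IntegerMatrix tips(n_tip, S);
  for (int i = 0; i < n_tip; ++i)
    for (int s = 0; s < S; ++s) tips(i, s) = states(i, s);
  IntegerVector pos(S);
  for (int s = 0; s < S; ++s) pos[s] = sites[s] + 1;
  return List::create(_["positions"] = pos, _["tips"] = tips,
                      _["root_base"] = root_base);
}
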