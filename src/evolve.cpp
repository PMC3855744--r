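#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Continuous-time evolution of the mitochondrial lattice network.
//
// Topology: each present edge is cut at rate k_fis, each absent candidate
// (lattice-neighbour) edge forms at rate k_fus. Because these propensities do
// not depend on the tracer field, the topology process is simulated exactly
// (Gillespie); between consecutive topology events the tracer obeys the linear
// mixing ODE da_i/dt = d_intra * sum_{j ~ i, edge present} (a_j - a_i),
// integrated with classical RK4 at a substep bounded by dt_max (supplied from
// R well inside the RK4 stability limit 2.78 / lambda_max, lambda_max <=
// 2 * d_intra * max_degree = 8 * d_intra on this lattice).
//
// Uses R's RNG so that set.seed() upstream makes trajectories bit-identical.

namespace {

struct Net {
  const int *ei, *ej;
  std::vector<int> pres, absent;
  std::vector<int> pos;  // index of each edge within its current set
  std::vector<char> isp;
};

// graph Laplacian action via the present-edge list (antisymmetric per edge,
// so the tracer total is conserved to round-off)
void laplacian(const Net &net, const std::vector<double> &x,
               std::vector<double> &out) {
  std::fill(out.begin(), out.end(), 0.0);
  for (size_t k = 0; k < net.pres.size(); ++k) {
    const int e = net.pres[k];
    const int i = net.ei[e], j = net.ej[e];
    const double f = x[j] - x[i];
    out[i] += f;
    out[j] -= f;
  }
}

struct Mixer {
  double d;
  std::vector<double> k1, k2, k3, k4, tmp;
  Mixer(int n, double d_intra) : d(d_intra), k1(n), k2(n), k3(n), k4(n), tmp(n) {}

  void advance(const Net &net, std::vector<double> &a, double dt,
               double dt_max) {
    if (d <= 0.0 || dt <= 0.0 || net.pres.empty()) return;
    int nsub = (int)std::ceil(dt / dt_max);
    if (nsub < 1) nsub = 1;
    const double h = dt / nsub;
    const int n = (int)a.size();
    for (int s = 0; s < nsub; ++s) {
      laplacian(net, a, k1);
      for (int i = 0; i < n; ++i) tmp[i] = a[i] + 0.5 * h * d * k1[i];
      laplacian(net, tmp, k2);
      for (int i = 0; i < n; ++i) tmp[i] = a[i] + 0.5 * h * d * k2[i];
      laplacian(net, tmp, k3);
      for (int i = 0; i < n; ++i) tmp[i] = a[i] + h * d * k3[i];
      laplacian(net, tmp, k4);
      for (int i = 0; i < n; ++i)
        a[i] += h * d * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]) / 6.0;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List evolve_cpp(IntegerVector edge_i, IntegerVector edge_j,
                LogicalVector present0, NumericVector a0, int n_nodes,
                double d_intra, double k_fis, double k_fus, double t_len,
                double dt_max) {
  const int E = edge_i.size();

  Net net;
  net.ei = edge_i.begin();
  net.ej = edge_j.begin();
  net.pos.resize(E);
  net.isp.resize(E);
  net.pres.reserve(E);
  net.absent.reserve(E);
  for (int e = 0; e < E; ++e) {
    net.isp[e] = present0[e] ? 1 : 0;
    if (net.isp[e]) {
      net.pos[e] = (int)net.pres.size();
      net.pres.push_back(e);
    } else {
      net.pos[e] = (int)net.absent.size();
      net.absent.push_back(e);
    }
  }

  std::vector<double> a(a0.begin(), a0.end());
  Mixer mixer(n_nodes, d_intra);
  const double inf = std::numeric_limits<double>::infinity();

  double t = 0.0;
  while (t < t_len) {
    const double np = (double)net.pres.size(), na = (double)net.absent.size();
    const double rtot = k_fis * np + k_fus * na;
    const double tau = (rtot > 0.0) ? R::exp_rand() / rtot : inf;
    if (t + tau >= t_len) {
      mixer.advance(net, a, t_len - t, dt_max);
      break;
    }
    mixer.advance(net, a, tau, dt_max);
    t += tau;

    const double u = R::unif_rand() * rtot;
    if (u < k_fis * np) {  // fission: deactivate a random present edge
      int r = (int)(R::unif_rand() * np);
      if (r >= (int)net.pres.size()) r = (int)net.pres.size() - 1;
      const int e = net.pres[r];
      const int last = net.pres.back();
      net.pres[r] = last;
      net.pos[last] = r;
      net.pres.pop_back();
      net.isp[e] = 0;
      net.pos[e] = (int)net.absent.size();
      net.absent.push_back(e);
    } else {  // fusion: activate a random absent edge
      int r = (int)(R::unif_rand() * na);
      if (r >= (int)net.absent.size()) r = (int)net.absent.size() - 1;
      const int e = net.absent[r];
      const int last = net.absent.back();
      net.absent[r] = last;
      net.pos[last] = r;
      net.absent.pop_back();
      net.isp[e] = 1;
      net.pos[e] = (int)net.pres.size();
      net.pres.push_back(e);
    }
  }

  double amin = 0.0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] < amin) amin = a[i];
  if (amin < -1e-9) stop("integrator instability: tracer went negative");

  LogicalVector present(E);
  for (int e = 0; e < E; ++e) present[e] = net.isp[e] != 0;
  return List::create(_["present"] = present,
                      _["tracer"] = NumericVector(a.begin(), a.end()));
}
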