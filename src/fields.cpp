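// Potential models on the lattice: screened-Coulomb (Debye-Hueckel) sums and
// a finite-difference linearized Poisson-Boltzmann solver (7-point stencil,
// successive over-relaxation).  Potentials are in kT/e; lvac is the vacuum
// Coulomb length e^2/(4 pi eps0 kB T) in Angstrom, so a unit charge in a
// uniform dielectric eps gives phi = lvac * q / (eps * d) kT/e.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_dh_field(NumericMatrix xyz, NumericVector q,
                           NumericVector origin, double spacing,
                           IntegerVector dims, double eps_solvent,
                           double kappa, double lvac, double clamp) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const int na = xyz.nrow();
  NumericVector out((long long)n1 * n2 * n3);
  long long idx = 0;
  for (int k = 0; k < n3; ++k) {
    double pz = origin[2] + spacing * k;
    for (int j = 0; j < n2; ++j) {
      double py = origin[1] + spacing * j;
      for (int i = 0; i < n1; ++i, ++idx) {
        double px = origin[0] + spacing * i;
        double phi = 0.0;
        for (int a = 0; a < na; ++a) {
          if (q[a] == 0.0) continue;
          double dx = px - xyz(a,0), dy = py - xyz(a,1), dz = pz - xyz(a,2);
          double d = std::sqrt(dx*dx + dy*dy + dz*dz);
          if (d < clamp) d = clamp;
          phi += lvac * q[a] * std::exp(-kappa * d) / (eps_solvent * d);
        }
        out[idx] = phi;
      }
    }
  }
  return out;
}

// Solve div(eps grad phi) - eps_solvent kappa^2 phi = -4 pi lvac rho with
// Dirichlet Debye-Hueckel boundary values.  eps is eps_solute inside the
// union of atom balls and eps_solvent outside; face permittivities are
// harmonic means; charges are spread trilinearly to the 8 surrounding nodes.
// The ionic term acts in solvent nodes only.  Returns phi plus convergence
// diagnostics; residual is the max Gauss-Seidel update of the final sweep.
// [[Rcpp::export]]
List cpp_fd_lpb(NumericMatrix xyz, NumericVector radii, NumericVector q,
                NumericVector origin, double spacing, IntegerVector dims,
                double eps_solute, double eps_solvent, double kappa,
                double lvac, double tol, int maxit, double omega) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long long N = (long long)n1 * n2 * n3;
  const double h = spacing;
  const int na = xyz.nrow();

  auto ix = [&](int i, int j, int k) -> long long {
    return (long long)i + (long long)n1 * (j + (long long)n2 * k);
  };

  // dielectric map: eps_solute inside any atom ball
  std::vector<double> eps(N, eps_solvent);
  std::vector<char> solvent(N, 1);
  for (int a = 0; a < na; ++a) {
    double r = radii[a];
    if (r <= 0) continue;
    int i0 = std::max(0, (int)std::ceil ((xyz(a,0) - r - origin[0]) / h));
    int i1 = std::min(n1 - 1, (int)std::floor((xyz(a,0) + r - origin[0]) / h));
    int j0 = std::max(0, (int)std::ceil ((xyz(a,1) - r - origin[1]) / h));
    int j1 = std::min(n2 - 1, (int)std::floor((xyz(a,1) + r - origin[1]) / h));
    int k0 = std::max(0, (int)std::ceil ((xyz(a,2) - r - origin[2]) / h));
    int k1 = std::min(n3 - 1, (int)std::floor((xyz(a,2) + r - origin[2]) / h));
    double r2 = r * r;
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + h*i - xyz(a,0);
          double dy = origin[1] + h*j - xyz(a,1);
          double dz = origin[2] + h*k - xyz(a,2);
          if (dx*dx + dy*dy + dz*dz <= r2) {
            eps[ix(i,j,k)] = eps_solute;
            solvent[ix(i,j,k)] = 0;
          }
        }
  }

  // trilinear charge spreading
  std::vector<double> rho(N, 0.0);
  for (int a = 0; a < na; ++a) {
    if (q[a] == 0.0) continue;
    double fi = (xyz(a,0) - origin[0]) / h;
    double fj = (xyz(a,1) - origin[1]) / h;
    double fk = (xyz(a,2) - origin[2]) / h;
    int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj),
        k0 = (int)std::floor(fk);
    double wi = fi - i0, wj = fj - j0, wk = fk - k0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          int i = i0 + di, j = j0 + dj, k = k0 + dk;
          if (i < 0 || i >= n1 || j < 0 || j >= n2 || k < 0 || k >= n3)
            continue;
          double w = (di ? wi : 1 - wi) * (dj ? wj : 1 - wj) *
                     (dk ? wk : 1 - wk);
          rho[ix(i,j,k)] += w * q[a];
        }
  }

  // initial guess and Dirichlet boundary: screened Coulomb sum
  std::vector<double> phi(N, 0.0);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double px = origin[0] + h*i, py = origin[1] + h*j,
               pz = origin[2] + h*k;
        double v = 0.0;
        for (int a = 0; a < na; ++a) {
          if (q[a] == 0.0) continue;
          double dx = px - xyz(a,0), dy = py - xyz(a,1), dz = pz - xyz(a,2);
          double d = std::sqrt(dx*dx + dy*dy + dz*dz);
          if (d < 0.5 * h) d = 0.5 * h;
          v += lvac * q[a] * std::exp(-kappa * d) / (eps_solvent * d);
        }
        phi[ix(i,j,k)] = v;
      }

  const double kap2h2 = eps_solvent * kappa * kappa * h * h;
  auto feps = [&](long long a, long long b) -> double {
    double ea = eps[a], eb = eps[b];
    return 2.0 * ea * eb / (ea + eb);
  };

  double resid = R_PosInf;
  int it = 0;
  for (it = 0; it < maxit && resid > tol; ++it) {
    resid = 0.0;
    for (int k = 1; k < n3 - 1; ++k)
      for (int j = 1; j < n2 - 1; ++j)
        for (int i = 1; i < n1 - 1; ++i) {
          long long c = ix(i,j,k);
          double exm = feps(c, ix(i-1,j,k)), exp_ = feps(c, ix(i+1,j,k));
          double eym = feps(c, ix(i,j-1,k)), eyp = feps(c, ix(i,j+1,k));
          double ezm = feps(c, ix(i,j,k-1)), ezp = feps(c, ix(i,j,k+1));
          double num = exm * phi[ix(i-1,j,k)] + exp_ * phi[ix(i+1,j,k)] +
                       eym * phi[ix(i,j-1,k)] + eyp * phi[ix(i,j+1,k)] +
                       ezm * phi[ix(i,j,k-1)] + ezp * phi[ix(i,j,k+1)] +
                       4.0 * M_PI * lvac * rho[c] / h;
          double den = exm + exp_ + eym + eyp + ezm + ezp +
                       (solvent[c] ? kap2h2 : 0.0);
          double gs = num / den;
          double d = gs - phi[c];
          if (std::fabs(d) > resid) resid = std::fabs(d);
          phi[c] += omega * d;
        }
  }
  return List::create(_["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["iterations"] = it, _["residual"] = resid,
                      _["converged"] = resid <= tol);
}
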