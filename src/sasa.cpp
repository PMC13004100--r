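#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible surface area, per atom.
//
// coords : n x 3 atom centres (angstrom)
// radii  : n vdW radii (angstrom)
// probe  : probe radius (angstrom)
// pts    : m x 3 unit vectors (deterministic spherical lattice)
//
// A test point on atom i's expanded sphere (radius r_i + probe) counts as
// accessible when it lies outside every neighbour's expanded sphere.
// Neighbour search is restricted to atoms with centre distance below
// r_i + r_j + 2*probe.
// [[Rcpp::export]]
NumericVector sasa_per_atom_cpp(NumericMatrix coords, NumericVector radii,
                                double probe, NumericMatrix pts) {
  const int n = coords.nrow();
  const int m = pts.nrow();
  NumericVector area(n);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  // flat copies avoid repeated Rcpp element dispatch in the hot loop
  std::vector<double> cx(n), cy(n), cz(n), px(m), py(m), pz(m);
  for (int i = 0; i < n; ++i) {
    cx[i] = coords(i, 0); cy[i] = coords(i, 1); cz[i] = coords(i, 2);
  }
  for (int k = 0; k < m; ++k) {
    px[k] = pts(k, 0); py[k] = pts(k, 1); pz[k] = pts(k, 2);
  }

  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = cx[i], yi = cy[i], zi = cz[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - cx[j];
      const double dy = yi - cy[j];
      const double dz = zi - cz[j];
      const double cut = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    const double Ri = R[i];
    for (int k = 0; k < m; ++k) {
      const double qx = xi + Ri * px[k];
      const double qy = yi + Ri * py[k];
      const double qz = zi + Ri * pz[k];
      bool free_pt = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = qx - cx[j];
        const double dy = qy - cy[j];
        const double dz = qz - cz[j];
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          free_pt = false;
          // the sphere that blocked this point likely blocks the next
          // lattice point too: move it to the front of the neighbour list
          if (q > 0) std::swap(nb[0], nb[q]);
          break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = (double)acc / (double)m * 4.0 * M_PI * Ri * Ri;
  }
  return area;
}
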