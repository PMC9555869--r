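// Kabsch superposition RMSD kernels used by the fixed-radius clustering loop.
// Coordinates are passed as A x 3 x F cubes (atoms, xyz, frames), Angstrom.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Minimized RMSD between two A x 3 coordinate sets (centered internally).
static double kabsch_rmsd(const mat &P, const mat &Q) {
  mat Pc = P.each_row() - mean(P, 0);
  mat Qc = Q.each_row() - mean(Q, 0);
  mat H = Pc.t() * Qc;
  mat U, V;
  vec s;
  if (!svd(U, s, V, H)) Rcpp::stop("SVD failed in RMSD computation");
  double d = det(V * U.t());
  double tr = s(0) + s(1) + (d < 0.0 ? -s(2) : s(2));
  double msd = (accu(square(Pc)) + accu(square(Qc)) - 2.0 * tr) /
               static_cast<double>(P.n_rows);
  return std::sqrt(std::max(msd, 0.0));
}

// Rotation R (3x3) such that centered(P) * R.t() best matches centered(Q).
static mat kabsch_rotation(const mat &P, const mat &Q) {
  mat Pc = P.each_row() - mean(P, 0);
  mat Qc = Q.each_row() - mean(Q, 0);
  mat H = Pc.t() * Qc;
  mat U, V;
  vec s;
  if (!svd(U, s, V, H)) Rcpp::stop("SVD failed in superposition");
  mat D = eye(3, 3);
  if (det(V * U.t()) < 0.0) D(2, 2) = -1.0;
  return V * D * U.t();
}

// [[Rcpp::export]]
double rmsd_pair_cpp(const arma::mat &p, const arma::mat &q) {
  return kabsch_rmsd(p, q);
}

// Sequential leader pass: assign each frame to the first centroid (a seed
// frame) within `radius`, else the frame seeds a new cluster. 1-based ids.
// [[Rcpp::export]]
Rcpp::List leader_cluster_cpp(const arma::cube &frames, double radius) {
  const uword F = frames.n_slices;
  Rcpp::IntegerVector assign(F);
  std::vector<uword> seeds;
  for (uword f = 0; f < F; ++f) {
    mat cur = frames.slice(f);
    int hit = -1;
    for (size_t k = 0; k < seeds.size(); ++k) {
      if (kabsch_rmsd(cur, frames.slice(seeds[k])) <= radius) {
        hit = static_cast<int>(k);
        break;
      }
    }
    if (hit < 0) {
      seeds.push_back(f);
      hit = static_cast<int>(seeds.size()) - 1;
    }
    assign[f] = hit + 1;
  }
  Rcpp::IntegerVector seed_idx(seeds.size());
  for (size_t k = 0; k < seeds.size(); ++k) seed_idx[k] = seeds[k] + 1;
  return Rcpp::List::create(Rcpp::Named("assign") = assign,
                            Rcpp::Named("seeds") = seed_idx);
}

// Nearest-centroid assignment. Ties within 1e-9 go to the lower cluster id.
// [[Rcpp::export]]
Rcpp::List assign_nearest_cpp(const arma::cube &frames,
                              const arma::cube &centroids) {
  const uword F = frames.n_slices, K = centroids.n_slices;
  Rcpp::IntegerVector id(F);
  Rcpp::NumericVector dist(F);
  for (uword f = 0; f < F; ++f) {
    mat cur = frames.slice(f);
    double best = datum::inf;
    uword best_k = 0;
    for (uword k = 0; k < K; ++k) {
      double r = kabsch_rmsd(cur, centroids.slice(k));
      if (r < best - 1e-9) {
        best = r;
        best_k = k;
      }
    }
    id[f] = best_k + 1;
    dist[f] = best;
  }
  return Rcpp::List::create(Rcpp::Named("id") = id,
                            Rcpp::Named("rmsd") = dist);
}

// RMSD of every frame to a single reference.
// [[Rcpp::export]]
arma::vec rmsd_to_ref_cpp(const arma::cube &frames, const arma::mat &ref) {
  vec out(frames.n_slices);
  for (uword f = 0; f < frames.n_slices; ++f)
    out(f) = kabsch_rmsd(frames.slice(f), ref);
  return out;
}

// Mean coordinates of the selected frames (1-based idx), each superposed
// onto `ref` first. Used for centroid refinement.
// [[Rcpp::export]]
arma::mat superposed_mean_cpp(const arma::cube &frames,
                              const arma::uvec &idx, const arma::mat &ref) {
  mat acc(ref.n_rows, 3, fill::zeros);
  rowvec refc = mean(ref, 0);
  for (uword i = 0; i < idx.n_elem; ++i) {
    mat P = frames.slice(idx(i) - 1);
    rowvec pc = mean(P, 0);
    mat R = kabsch_rotation(P, ref);
    mat aligned = (P.each_row() - pc) * R.t();
    aligned.each_row() += refc;
    acc += aligned;
  }
  return acc / static_cast<double>(idx.n_elem);
}
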