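#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential stochastic-gradient layout optimisation for UMAP.
// Follows the reference scheme: each positive edge is visited with a
// frequency proportional to its membership weight (epochs-per-sample
// bookkeeping), both endpoints move on attraction, and each visit draws
// `negative_sample_rate` uniform vertices that repel the head. Uses R's
// RNG so layouts are reproducible under set.seed().
//
// head/tail are 0-based directed edge endpoints; embedding is modified in
// place and returned.
// [[Rcpp::export(name = ".umap_optimize_layout")]]
NumericMatrix umap_optimize_layout(NumericMatrix embedding,
                                   IntegerVector head,
                                   IntegerVector tail,
                                   NumericVector epochs_per_sample,
                                   int n_epochs,
                                   double a,
                                   double b,
                                   double initial_alpha,
                                   double negative_sample_rate,
                                   double repulsion_strength) {
  const int n_vertices = embedding.nrow();
  const int dim = embedding.ncol();
  const int n_edges = head.size();
  std::vector<double> epoch_of_next_sample(epochs_per_sample.begin(),
                                           epochs_per_sample.end());
  std::vector<double> epochs_per_negative_sample(n_edges);
  std::vector<double> epoch_of_next_negative_sample(n_edges);
  for (int i = 0; i < n_edges; ++i) {
    epochs_per_negative_sample[i] = epochs_per_sample[i] / negative_sample_rate;
    epoch_of_next_negative_sample[i] = epochs_per_negative_sample[i];
  }
  GetRNGstate();
  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    double alpha = initial_alpha * (1.0 - (double)(epoch - 1) / n_epochs);
    for (int i = 0; i < n_edges; ++i) {
      if (epoch_of_next_sample[i] > epoch) continue;
      int j = head[i];
      int k = tail[i];
      double d2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        double diff = embedding(j, d) - embedding(k, d);
        d2 += diff * diff;
      }
      if (d2 > 0.0) {
        double grad_coeff = (-2.0 * a * b * std::pow(d2, b - 1.0)) /
                            (a * std::pow(d2, b) + 1.0);
        for (int d = 0; d < dim; ++d) {
          double g = grad_coeff * (embedding(j, d) - embedding(k, d));
          if (g > 4.0) g = 4.0; else if (g < -4.0) g = -4.0;
          embedding(j, d) += alpha * g;
          embedding(k, d) -= alpha * g;
        }
      }
      epoch_of_next_sample[i] += epochs_per_sample[i];
      int n_neg = (int)((epoch - epoch_of_next_negative_sample[i]) /
                        epochs_per_negative_sample[i]);
      for (int p = 0; p < n_neg; ++p) {
        int t = (int)(unif_rand() * n_vertices);
        if (t >= n_vertices) t = n_vertices - 1;
        if (t == j) continue;
        double dn2 = 0.0;
        for (int d = 0; d < dim; ++d) {
          double diff = embedding(j, d) - embedding(t, d);
          dn2 += diff * diff;
        }
        double grad_coeff = 0.0;
        if (dn2 > 0.0)
          grad_coeff = (2.0 * repulsion_strength * b) /
                       ((0.001 + dn2) * (a * std::pow(dn2, b) + 1.0));
        for (int d = 0; d < dim; ++d) {
          double g;
          if (grad_coeff > 0.0) {
            g = grad_coeff * (embedding(j, d) - embedding(t, d));
            if (g > 4.0) g = 4.0; else if (g < -4.0) g = -4.0;
          } else {
            g = 4.0;
          }
          embedding(j, d) += alpha * g;
        }
      }
      epoch_of_next_negative_sample[i] +=
          n_neg * epochs_per_negative_sample[i];
    }
  }
  PutRNGstate();
  return embedding;
}
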