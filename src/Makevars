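# Use the Eigen headers shipped with the environment when available; the
# C++ code falls back to an R-level solve when HAVE_EIGEN is undefined.
EIGEN_INC := $(shell "${R_HOME}/bin/Rscript" --vanilla -e 'p<-suppressWarnings(normalizePath(file.path(R.home(),"..","..","include","eigen3"),mustWork=FALSE)); if (file.exists(file.path(p,"Eigen","Sparse"))) cat("-I", p, " -DHAVE_EIGEN", sep="")')
PKG_CPPFLAGS = $(EIGEN_INC)
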