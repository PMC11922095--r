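# raise optimisation for the compute kernels; -march=native targets the
# machine the package is installed on (kernels are compiled from source)
override CXXFLAGS += -O3 -funroll-loops
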